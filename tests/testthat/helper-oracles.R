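# Independent oracles and fixture builders. Everything here deliberately
# avoids the package's own dynamic-programming / bipartition code paths.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

random_protein <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# mutate a sequence at exactly k positions (guaranteed different residue)
mutate_seq <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1)
  paste(ch, collapse = "")
}

# ---- brute-force affine global alignment score -----------------------------
# Enumerates every monotone alignment as a move string (M = substitute,
# X = gap in b, Y = gap in a) and scores it directly: substitution scores
# from the matrix, each maximal gap run costing open + len * ext. Exponential;
# only usable for sequences of length <= 4.
brute_force_align_score <- function(a, b, scheme = arsafam::scoring_scheme()) {
  S <- scheme$matrix
  open <- scheme$gap_open
  ext <- scheme$gap_extend
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, moves) {
    if (i == length(ca) && j == length(cb)) {
      sc <- 0
      run <- ""
      ii <- 0L; jj <- 0L
      for (m in moves) {
        if (m == "M") {
          ii <- ii + 1L; jj <- jj + 1L
          sc <- sc + S[ca[ii], cb[jj]]
        } else {
          if (m == "X") ii <- ii + 1L else jj <- jj + 1L
          sc <- sc - ext - if (run == m) 0 else open
        }
        run <- m
      }
      best <<- max(best, sc)
      return(invisible())
    }
    if (i < length(ca) && j < length(cb)) recurse(i + 1L, j + 1L, c(moves, "M"))
    if (i < length(ca)) recurse(i + 1L, j, c(moves, "X"))
    if (j < length(cb)) recurse(i, j + 1L, c(moves, "Y"))
  }
  recurse(0L, 0L, character(0))
  if (length(ca) == 0L && length(cb) == 0L) 0 else best
}

# ---- brute-force Robinson-Foulds via explicit bipartition sets -------------
# Extracts every non-trivial split of an unrooted tree by listing, for each
# internal edge, the tip labels below it, canonicalized so the side holding
# the alphabetically first tip represents the split.
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  tips_below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  all_tips <- sort(tree$tip.label)
  splits <- character(0)
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2]
    if (child <= ntip) next  # trivial split
    side <- sort(tips_below(child))
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (!(all_tips[1L] %in% side)) side <- setdiff(all_tips, side)
    splits <- c(splits, paste(sort(side), collapse = "|"))
  }
  unique(splits)
}

brute_force_rf <- function(tree_a, tree_b) {
  sa <- tree_splits(tree_a)
  sb <- tree_splits(tree_b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

# ---- brute-force degenerate-pattern scan -----------------------------------
brute_force_pattern_scan <- function(seq, sets) {
  ch <- strsplit(seq, "")[[1]]
  w <- length(sets)
  hits <- integer(0)
  if (length(ch) < w) return(hits)
  for (s in seq_len(length(ch) - w + 1L)) {
    if (all(mapply(function(c, set) c %in% set, ch[s:(s + w - 1L)], sets)))
      hits <- c(hits, s)
  }
  hits
}

# ---- fixtures ---------------------------------------------------------------
# a strictly positive-branch random tree and its additive distance matrix
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) runif(n, 0.1, 1))
  tr$tip.label <- sample(paste0("t", seq_len(n_taxa)))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# caterpillar (ladder) tree over the given labels, unit branch lengths
caterpillar_tree <- function(labels) {
  n <- length(labels)
  txt <- paste0(labels[n], ":1")
  for (k in (n - 1L):2L) txt <- paste0("(", labels[k], ":1,", txt, "):1")
  ape::read.tree(text = paste0("(", labels[1L], ":1,", txt, ");"))
}

# write a small catalog TSV for parse tests
write_catalog_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- "abbrev\torganism\tsize_aa\torganism_type\tgi\tcluster_id"
  writeLines(c(header, rows), path)
  path
}
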