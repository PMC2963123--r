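#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei neighbor joining: at each step the pair minimizing the
#' Q-criterion `(r-2) d_ij - R_i - R_j` is joined, the two new branch lengths
#' come from the standard two-point formulas, and the matrix is reduced.
#' Ties in the Q-criterion are broken lexicographically by the smallest taxon
#' id contained in each candidate subtree, so the output is deterministic.
#' Negative branch-length estimates are clamped to zero and the deficit moved
#' to the sibling branch, preserving the joined pair's path length.
#'
#' @param D Symmetric numeric matrix with zero diagonal, finite nonnegative
#'   entries, and identical row/column names (at least 2 taxa).
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
#' @examples
#' D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' neighbor_joining(D)  # branches 0.5, 1.5, 2.5
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 taxa")
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  }
  if (!identical(rownames(D), colnames(D)))
    stop("row and column names must match")
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries")
  if (any(D < 0)) stop("distance matrix has negative entries")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be zero")

  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  # each active node: newick fragment + lexicographically smallest member id
  frag <- rownames(D)
  key <- rownames(D)

  join_lengths <- function(dij, ri, rj, r) {
    li <- dij / 2 + (ri - rj) / (2 * (r - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(li, lj)
  }

  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    kpair <- t(apply(cand, 1L, function(ij) sort(key[ij])))
    ord <- order(kpair[, 1L], kpair[, 2L])
    i <- cand[ord[1L], 1L]; j <- cand[ord[1L], 2L]
    l <- join_lengths(D[i, j], R[i], R[j], r)
    newfrag <- paste0("(", frag[i], ":", fmt(l[1]), ",",
                      frag[j], ":", fmt(l[2]), ")")
    newkey <- min(key[i], key[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
    rownames(D2) <- colnames(D2) <- make.unique(c(key))
    D <- D2
  }

  if (nrow(D) == 3L) {
    la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    l <- pmax(c(la, lb, lc), 0)
    nwk <- paste0("(", frag[1], ":", fmt(l[1]), ",", frag[2], ":", fmt(l[2]),
                  ",", frag[3], ":", fmt(l[3]), ");")
  } else {
    l <- D[1, 2] / 2
    nwk <- paste0("(", frag[1], ":", fmt(l), ",", frag[2], ":", fmt(l), ");")
  }
  ape::read.tree(text = nwk)
}

#' Patristic (cophenetic) distance matrix of a tree
#'
#' Sum of branch lengths along the path between every pair of leaves.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param order Optional character vector of tip labels fixing row order.
#' @return Symmetric matrix with tip labels as dimnames.
#' @export
patristic_matrix <- function(tree, order = NULL) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  m <- ape::cophenetic.phylo(tree)
  if (!is.null(order)) {
    if (!all(order %in% rownames(m))) stop("unknown tip label in 'order'")
    m <- m[order, order]
  }
  m
}

#' Parse, serialize, and round-trip Newick trees
#'
#' `read_newick` validates balanced parentheses and duplicate leaf labels
#' before handing the text to `ape`, reporting the character offset of a
#' parenthesis imbalance. `newick_roundtrip` parses and re-serializes,
#' returning the canonical string.
#'
#' @param text A Newick string (terminated by `;`).
#' @return `read_newick`: an `ape::phylo`; `write_newick`: a Newick string.
#' @export
read_newick <- function(text) {
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced ')' at offset ", k)
  }
  if (depth != 0L)
    stop("unbalanced '(' : ", depth, " unclosed at end of string (length ",
         length(chars), ")")
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("Newick parse failure")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label: ", tr$tip.label[duplicated(tr$tip.label)][1L])
  tr
}

#' @rdname read_newick
#' @param tree An `ape::phylo`.
#' @export
write_newick <- function(tree) ape::write.tree(tree)

#' @rdname read_newick
#' @export
newick_roundtrip <- function(text) write_newick(read_newick(text))

#' Read / write a square TSV distance matrix
#'
#' Square matrix with taxon ids in the first column and the header row
#' (PHYLIP-style square layout with named rows is also accepted).
#' @param path File path.
#' @export
read_distance_tsv <- function(path) {
  d <- read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(d)
  colnames(m) <- colnames(d)
  storage.mode(m) <- "double"
  m
}

#' @rdname read_distance_tsv
#' @param D Square matrix with dimnames.
#' @export
write_distance_tsv <- function(D, path) {
  write.table(data.frame(id = rownames(D), D, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
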