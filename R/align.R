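#' Construct an alignment scoring scheme
#'
#' Affine gap model: a gap of length L costs `gap_open + L * gap_extend`.
#' Defaults follow common protein-search practice (BLOSUM62, 11/1).
#'
#' @param substitution_matrix Symmetric integer substitution matrix with
#'   residue row/column names. Defaults to BLOSUM62 (from Biostrings),
#'   restricted to the 20 standard residues plus B, Z, X.
#' @param gap_open Nonnegative gap-opening penalty.
#' @param gap_extend Nonnegative per-residue gap-extension penalty; must not
#'   exceed `gap_open`.
#' @return An object of class `"scoring_scheme"`.
#' @export
scoring_scheme <- function(substitution_matrix = blosum62(),
                           gap_open = 11, gap_extend = 1) {
  m <- as.matrix(substitution_matrix)
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop("substitution matrix needs identical residue row/column names")
  if (!isTRUE(all.equal(m, t(m)))) stop("substitution matrix must be symmetric")
  if (gap_open < 0 || gap_extend < 0 || gap_extend > gap_open)
    stop("need 0 <= gap_extend <= gap_open")
  structure(list(matrix = m, gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' BLOSUM62 substitution matrix over the protein alphabet
#'
#' @return The BLOSUM62 matrix restricted to A..V plus B, Z, X.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[.AAX, .AAX]
}

aa_encode <- function(seq, alphabet) {
  if (!is.character(seq) || length(seq) != 1L) stop("sequence must be a string")
  ch <- strsplit(toupper(seq), "")[[1]]
  idx <- match(ch, alphabet)
  if (anyNA(idx))
    stop("illegal residue '", ch[which(is.na(idx))[1L]], "' in sequence")
  idx
}

#' Global pairwise protein alignment (Needleman-Wunsch, affine gaps)
#'
#' Terminal gaps are penalized (classic global alignment); percent identity is
#' computed over alignment columns excluding terminal gap columns, so
#' fragments aligned inside a longer sequence are scored over the overlap.
#' Ties in the dynamic program are broken deterministically, preferring a
#' substitution over a gap in the second sequence over a gap in the first.
#'
#' @param a,b Protein sequences (strings over the amino-acid alphabet;
#'   X allowed).
#' @param scheme A [scoring_scheme()].
#' @return A list of class `"pairwise_alignment"`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`, `identity` (in `[0,1]`).
#' @export
#' @examples
#' global_align("ACDE", "ACDE")$identity  # 1
global_align <- function(a, b, scheme = scoring_scheme()) {
  alph <- rownames(scheme$matrix)
  ia <- aa_encode(a, alph)
  ib <- aa_encode(b, alph)
  if (length(ia) == 0L && length(ib) == 0L) {
    return(structure(list(aligned_a = "", aligned_b = "", score = 0,
                          identity = NA_real_),
                     class = "pairwise_alignment"))
  }
  r <- .nw_align_cpp(ia, ib, scheme$matrix, scheme$gap_open, scheme$gap_extend)
  ca <- ifelse(r$path_a == 0L, "-", alph[ia[pmax(r$path_a, 1L)]])
  cb <- ifelse(r$path_b == 0L, "-", alph[ib[pmax(r$path_b, 1L)]])
  structure(list(aligned_a = paste(ca, collapse = ""),
                 aligned_b = paste(cb, collapse = ""),
                 score = r$score,
                 identity = alignment_identity(ca, cb)),
            class = "pairwise_alignment")
}

# identity = matching residue columns / columns, excluding terminal gap runs
alignment_identity <- function(ca, cb) {
  n <- length(ca)
  if (n == 0L) return(NA_real_)
  core <- which(ca != "-" & cb != "-")
  if (length(core) == 0L) return(0)
  keep <- seq(min(core), max(core))
  sum(ca[keep] == cb[keep] & ca[keep] != "-") / length(keep)
}

#' Poisson-corrected evolutionary distance from percent identity
#'
#' `d = -log(identity)`, the Poisson correction of the observed proportion of
#' identical sites. Zero identity would be infinite and is replaced by `cap`
#' with a warning.
#'
#' @param identity Fraction in `[0,1]` (vectorized).
#' @param cap Replacement for the identity-0 singularity (default 10).
#' @return Nonnegative distance(s).
#' @export
poisson_distance <- function(identity, cap = 10) {
  if (any(identity < 0 | identity > 1, na.rm = TRUE))
    stop("identity must lie in [0,1]")
  d <- -log(identity)
  if (any(is.infinite(d), na.rm = TRUE)) {
    warning("identity 0 capped at distance ", cap)
    d[is.infinite(d)] <- cap
  }
  pmin(d, cap)
}

#' Score-based distance between two sequences
#'
#' A normalized-score distance in the spirit of bit-score based family trees:
#' `d = 1 - S(a,b) / max(S(a,a), S(b,b))`, floored at 0. Identical sequences
#' are at distance 0; the measure is symmetric.
#'
#' @inheritParams global_align
#' @return Nonnegative distance.
#' @export
score_distance <- function(a, b, scheme = scoring_scheme()) {
  sab <- global_align(a, b, scheme)$score
  saa <- global_align(a, a, scheme)$score
  sbb <- global_align(b, b, scheme)$score
  max(0, 1 - sab / max(saa, sbb))
}

#' All-pairs identity and Poisson distance matrices
#'
#' @param seqs Named character vector of protein sequences.
#' @param scheme A [scoring_scheme()].
#' @param cap Passed to [poisson_distance()].
#' @return List with symmetric matrices `identity` and `distance`.
#' @export
pairwise_distances <- function(seqs, scheme = scoring_scheme(), cap = 10) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  n <- length(seqs)
  idm <- matrix(1, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      idm[i, j] <- idm[j, i] <- global_align(seqs[[i]], seqs[[j]], scheme)$identity
    }
  }
  d <- suppressWarnings(matrix(poisson_distance(idm, cap), n, n,
                               dimnames = dimnames(idm)))
  diag(d) <- 0
  list(identity = idm, distance = d)
}

msa_rows_to_profile <- function(rows, alph) {
  # sparse per-column residue frequencies over non-gap rows; gaps contribute
  # nothing, so a column's total frequency equals its non-gap fraction
  L <- length(rows[[1]])
  res <- integer(0); frq <- numeric(0); off <- integer(L + 1L)
  nr <- length(rows)
  for (c in seq_len(L)) {
    col <- vapply(rows, `[`, character(1), c)
    col <- col[col != "-"]
    off[c] <- length(res)
    if (length(col)) {
      t <- table(match(col, alph))
      res <- c(res, as.integer(names(t)))
      frq <- c(frq, as.numeric(t) / nr)
    }
  }
  off[L + 1L] <- length(res)
  list(res = res, frq = frq, off = off)
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree by neighbor joining on Poisson-corrected pairwise
#' identities, then merges alignments in guide-tree postorder by
#' profile-profile affine alignment under the sum-of-pairs score (gap
#' characters contribute zero substitution score; gap penalties apply at the
#' profile level). Fully deterministic.
#'
#' @param seqs Named character vector of at least one protein sequence.
#' @param scheme A [scoring_scheme()].
#' @return Object of class `"msa"`: list with `ids` and `rows` (named
#'   character vector of equal-length gapped strings) and `ncol`.
#' @export
progressive_msa <- function(seqs, scheme = scoring_scheme()) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  alph <- rownames(scheme$matrix)
  if (length(seqs) == 1L)
    return(new_msa(setNames(toupper(unname(seqs)), names(seqs))))
  if (length(seqs) == 2L) {
    al <- global_align(seqs[[1]], seqs[[2]], scheme)
    return(new_msa(setNames(c(al$aligned_a, al$aligned_b), names(seqs))))
  }
  pd <- pairwise_distances(seqs, scheme)
  guide <- neighbor_joining(pd$distance)
  guide <- ape::root(guide, outgroup = guide$tip.label[1L], resolve.root = TRUE)
  merge_node <- function(node) {
    # returns list of gapped character-vector rows, named
    if (node <= length(guide$tip.label)) {
      id <- guide$tip.label[node]
      return(setNames(list(strsplit(toupper(seqs[[id]]), "")[[1]]), id))
    }
    kids <- guide$edge[guide$edge[, 1] == node, 2]
    prof <- merge_node(kids[1])
    for (k in kids[-1]) prof <- merge_profiles(prof, merge_node(k), scheme, alph)
    prof
  }
  root <- length(guide$tip.label) + 1L
  rows <- merge_node(root)
  rows <- rows[names(seqs)[names(seqs) %in% names(rows)]]
  new_msa(vapply(rows, paste, character(1), collapse = ""))
}

merge_profiles <- function(ra, rb, scheme, alph) {
  pa <- msa_rows_to_profile(ra, alph)
  pb <- msa_rows_to_profile(rb, alph)
  r <- .profile_align_cpp(pa$res, pa$frq, pa$off, pb$res, pb$frq, pb$off,
                          scheme$matrix, scheme$gap_open, scheme$gap_extend)
  expand <- function(rows, path) {
    lapply(rows, function(v) {
      out <- rep("-", length(path))
      out[path != 0L] <- v[path[path != 0L]]
      out
    })
  }
  c(expand(ra, r$path_a), expand(rb, r$path_b))
}

new_msa <- function(rows) {
  w <- unique(nchar(rows))
  stopifnot(length(w) == 1L)
  structure(list(ids = names(rows), rows = rows, ncol = w), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa: ", length(x$rows), " sequences x ", x$ncol, " columns\n", sep = "")
  invisible(x)
}

#' Map a reference residue position to an alignment column
#'
#' Reference positions are 1-based ungapped coordinates in the named row
#' (matching usage such as "C113 of the E. coli protein"); the returned MSA
#' column index is 0-based.
#'
#' @param msa An [progressive_msa()] result (or any `"msa"` object).
#' @param ref_id Row id of the reference sequence.
#' @param ref_pos 1-based position in the ungapped reference sequence.
#' @return 0-based column index.
#' @export
map_reference_column <- function(msa, ref_id, ref_pos) {
  if (!ref_id %in% names(msa$rows)) stop("reference id not in MSA: ", ref_id)
  ch <- strsplit(msa$rows[[ref_id]], "")[[1]]
  nong <- which(ch != "-")
  if (ref_pos < 1L || ref_pos > length(nong))
    stop("ref_pos ", ref_pos, " beyond ungapped length ", length(nong),
         " of ", ref_id)
  nong[ref_pos] - 1L
}

#' Read / write FASTA protein files
#'
#' Thin wrappers over Biostrings returning plain named character vectors.
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector (gapped rows allowed).
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
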