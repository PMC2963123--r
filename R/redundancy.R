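#' Remove redundant, near-identical, and fragmentary sequences
#'
#' Greedy representative selection emulating a 90%-identity redundancy
#' screen. Candidates are visited in descending length order (ties broken by
#' name, lexicographically, so the result is independent of input order). A
#' candidate is dropped when its global-alignment percent identity to any
#' already-retained sequence reaches `cutoff`, or when it is a fragment of a
#' retained sequence: shorter than `fragment_fraction` times that sequence's
#' length while still matching it at `cutoff` identity over the aligned
#' region (identity excludes terminal gap columns, so fragments are scored
#' over their overlap).
#'
#' @param seqs Named character vector of protein sequences.
#' @param cutoff Identity cutoff in `(0, 1]` (default 0.9).
#' @param fragment_fraction Length fraction below which a matching sequence
#'   counts as a fragment (default 0.6).
#' @param scheme A [scoring_scheme()].
#' @return The retained subset of `seqs`, in selection order.
#' @export
filter_redundant <- function(seqs, cutoff = 0.9, fragment_fraction = 0.6,
                             scheme = scoring_scheme()) {
  if (length(seqs) == 0L) return(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]")
  if (fragment_fraction <= 0 || fragment_fraction > 1)
    stop("fragment_fraction must lie in (0, 1]")
  ord <- order(-nchar(seqs), names(seqs))
  kept <- character(0)
  for (nm in names(seqs)[ord]) {
    cand <- seqs[[nm]]
    drop <- FALSE
    for (km in kept) {
      idy <- global_align(cand, seqs[[km]], scheme)$identity
      if (is.na(idy)) next
      redundant <- idy >= cutoff
      fragment <- nchar(cand) < fragment_fraction * nchar(seqs[[km]]) &&
        idy >= cutoff
      if (redundant || fragment) { drop <- TRUE; break }
    }
    if (!drop) kept <- c(kept, nm)
  }
  seqs[kept]
}
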