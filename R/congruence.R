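#' Construct a leaf pairing between two trees
#'
#' A pairing links leaves of one family's tree to leaves of another family's
#' tree, typically one pair per operon that encodes both families. Each leaf
#' may appear in at most one pair.
#'
#' @param leaf_a,leaf_b Character vectors of equal length: matched leaf ids.
#' @param operon_id Optional per-pair source operon identifier.
#' @return A data.frame of class `"leaf_pairing"`.
#' @export
leaf_pairing <- function(leaf_a, leaf_b, operon_id = NULL) {
  stopifnot(length(leaf_a) == length(leaf_b))
  if (anyDuplicated(leaf_a) || anyDuplicated(leaf_b))
    stop("each leaf may appear in at most one pair")
  out <- data.frame(leaf_a = as.character(leaf_a),
                    leaf_b = as.character(leaf_b),
                    stringsAsFactors = FALSE)
  out$operon_id <- if (is.null(operon_id))
    rep(NA_character_, nrow(out)) else as.character(operon_id)
  class(out) <- c("leaf_pairing", class(out))
  out
}

prune_and_relabel <- function(tree_a, tree_b, pairing) {
  miss_a <- setdiff(pairing$leaf_a, tree_a$tip.label)
  miss_b <- setdiff(pairing$leaf_b, tree_b$tip.label)
  if (length(miss_a) || length(miss_b))
    stop("pairing names leaves absent from the trees: ",
         paste(c(miss_a, miss_b), collapse = ", "))
  ta <- ape::keep.tip(tree_a, pairing$leaf_a)
  tb <- ape::keep.tip(tree_b, pairing$leaf_b)
  # rename B leaves to their A partners so bipartitions are comparable
  tb$tip.label <- pairing$leaf_a[match(tb$tip.label, pairing$leaf_b)]
  list(a = ape::unroot(ta), b = ape::unroot(tb))
}

#' Robinson-Foulds distance between two paired trees
#'
#' Both trees are pruned to the paired leaves, the second tree's leaves are
#' relabeled to their partners, and the symmetric difference of non-trivial
#' bipartitions is counted. The normalized distance divides by the maximum
#' `2 (n - 3)` for `n` paired leaves.
#'
#' @param tree_a,tree_b `ape::phylo` trees.
#' @param pairing A [leaf_pairing()] with at least 4 pairs.
#' @return List with `rf` (even nonnegative integer) and `rf_normalized`.
#' @export
robinson_foulds <- function(tree_a, tree_b, pairing) {
  if (nrow(pairing) < 4L) stop("need at least 4 leaf pairs")
  pr <- prune_and_relabel(tree_a, tree_b, pairing)
  rf <- as.integer(phangorn::RF.dist(pr$a, pr$b, check.labels = TRUE))
  n <- nrow(pairing)
  denom <- 2L * (n - 3L)
  list(rf = rf, rf_normalized = if (denom > 0) rf / denom else NA_real_)
}

#' Cophenetic (mirror-tree) congruence between two paired trees
#'
#' Pearson correlation between the patristic distances of matched leaf pairs
#' in the two trees - the classic mirror-tree statistic. Insensitive to
#' overall rate: rescaling all branch lengths of either tree leaves it
#' unchanged.
#'
#' @inheritParams robinson_foulds
#' @return Correlation in `[-1, 1]`, or `NA` if either distance vector has
#'   zero variance (inconclusive).
#' @export
cophenetic_congruence <- function(tree_a, tree_b, pairing) {
  if (nrow(pairing) < 4L) stop("need at least 4 leaf pairs")
  va <- pairing_patristic(tree_a, pairing$leaf_a)
  vb <- pairing_patristic(tree_b, pairing$leaf_b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
  stats::cor(va, vb)
}

pairing_patristic <- function(tree, leaves) {
  m <- patristic_matrix(tree, order = leaves)
  m[lower.tri(m)]
}

#' Permutation test for tree congruence (coevolution)
#'
#' The observed statistic is the cophenetic correlation under the given
#' pairing (the Robinson-Foulds distance is reported alongside). The null
#' distribution is obtained by randomly permuting the B side of the pairing
#' `n_perm` times; `p = (1 + #(null >= observed)) / (n_perm + 1)`. The verdict
#' is `"coevolved"` when `p <= alpha`, `"not_coevolved"` otherwise, and
#' `"inconclusive"` when a distance vector has zero variance.
#'
#' @inheritParams robinson_foulds
#' @param pairing A [leaf_pairing()] with at least 5 pairs.
#' @param n_perm Number of permutations, at least 99.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param alpha Significance level for the verdict (default 0.05).
#' @return List of class `"congruence_result"`: `rf`, `rf_normalized`,
#'   `cophenetic_r`, `p_value`, `verdict`, `n_pairs`, `n_perm`, `alpha`.
#' @export
permutation_test <- function(tree_a, tree_b, pairing, n_perm = 999, seed,
                             alpha = 0.05) {
  if (missing(seed)) stop("seed is required")
  if (n_perm < 99L) stop("n_perm must be at least 99")
  if (nrow(pairing) < 5L) stop("need at least 5 leaf pairs")
  rfres <- robinson_foulds(tree_a, tree_b, pairing)
  va <- pairing_patristic(tree_a, pairing$leaf_a)
  vb_mat <- patristic_matrix(tree_b, order = pairing$leaf_b)
  vb <- vb_mat[lower.tri(vb_mat)]
  n <- nrow(pairing)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    return(structure(c(rfres, list(cophenetic_r = NA_real_,
                                   p_value = NA_real_,
                                   verdict = "inconclusive",
                                   n_pairs = n, n_perm = n_perm,
                                   alpha = alpha)),
                     class = "congruence_result"))
  }
  obs <- stats::cor(va, vb)
  set.seed(as.integer(seed))
  null <- vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    m <- vb_mat[p, p]
    stats::cor(va, m[lower.tri(m)])
  }, numeric(1))
  p <- (1 + sum(null >= obs)) / (n_perm + 1)
  structure(c(rfres, list(cophenetic_r = obs, p_value = p,
                          verdict = if (p <= alpha) "coevolved" else
                            "not_coevolved",
                          n_pairs = n, n_perm = n_perm, alpha = alpha)),
            class = "congruence_result")
}

#' @export
print.congruence_result <- function(x, ...) {
  cat(sprintf(
    "tree congruence over %d pairs: RF = %d (norm %.3f), cophenetic r = %.3f\n",
    x$n_pairs, x$rf, x$rf_normalized, x$cophenetic_r))
  cat(sprintf("permutation p = %.4g (%d perms, alpha %.2f) -> %s\n",
              x$p_value, x$n_perm, x$alpha, x$verdict))
  invisible(x)
}

#' Resolve paralogue ambiguity by maximal observed congruence
#'
#' When an operon offers several candidate pairs (paralogues), every
#' combination of one candidate per operon is scored and the pairing with the
#' highest cophenetic correlation is returned, flagged as post-hoc (it must
#' not be treated as an unbiased estimate). Candidates sharing an
#' `operon_id` are the alternatives; at most `max_combos` combinations are
#' evaluated exhaustively, beyond which a greedy per-operon choice is made.
#'
#' @param tree_a,tree_b `ape::phylo` trees.
#' @param candidates Data.frame with `leaf_a`, `leaf_b`, `operon_id`, possibly
#'   several rows per operon.
#' @param max_combos Exhaustive-search cap.
#' @return A [leaf_pairing()] with attribute `post_hoc = TRUE` and
#'   `cophenetic_r` of the chosen pairing.
#' @export
select_best_pairing <- function(tree_a, tree_b, candidates, max_combos = 256) {
  sp <- split(seq_len(nrow(candidates)), candidates$operon_id)
  sizes <- vapply(sp, length, integer(1))
  score_pairing <- function(rows) {
    pr <- candidates[rows, , drop = FALSE]
    if (anyDuplicated(pr$leaf_a) || anyDuplicated(pr$leaf_b)) return(-Inf)
    cophenetic_congruence(tree_a, tree_b,
                          leaf_pairing(pr$leaf_a, pr$leaf_b, pr$operon_id))
  }
  if (prod(sizes) <= max_combos) {
    combos <- expand.grid(lapply(sp, seq_along), KEEP.OUT.ATTRS = FALSE)
    best <- -Inf; best_rows <- NULL
    for (k in seq_len(nrow(combos))) {
      rows <- mapply(function(ix, ch) ix[ch], sp, as.integer(combos[k, ]))
      s <- score_pairing(rows)
      if (!is.na(s) && s > best) { best <- s; best_rows <- rows }
    }
  } else {
    # greedy: fix singleton operons, then choose per ambiguous operon in order
    best_rows <- vapply(sp, `[`, integer(1), 1L)
    for (op in names(sp)[sizes > 1L]) {
      sc <- vapply(sp[[op]], function(rw) {
        rows <- best_rows; rows[match(op, names(sp))] <- rw
        score_pairing(rows)
      }, numeric(1))
      best_rows[match(op, names(sp))] <- sp[[op]][which.max(sc)]
    }
    best <- score_pairing(best_rows)
  }
  if (is.null(best_rows)) stop("no consistent pairing among candidates")
  pr <- candidates[best_rows, , drop = FALSE]
  out <- leaf_pairing(pr$leaf_a, pr$leaf_b, pr$operon_id)
  attr(out, "post_hoc") <- TRUE
  attr(out, "cophenetic_r") <- best
  out
}
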