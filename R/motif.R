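#' Ungapped motif discovery by expectation-maximization (OOPS model)
#'
#' Finds one ungapped motif of fixed width assuming exactly one occurrence per
#' sequence (OOPS). The E-step computes, per sequence, the posterior over
#' start positions from the current frequency matrix against a 0-order
#' background; the M-step re-estimates residue frequencies from the
#' posterior-weighted windows with a pseudocount of 0.01 per cell. The best of
#' `n_starts` seeded restarts (by final log-likelihood) is returned. The
#' log-likelihood is asserted non-decreasing across iterations.
#'
#' @param seqs Character vector of at least 2 protein sequences, each at
#'   least `width` long.
#' @param width Motif width (positive integer).
#' @param n_starts Number of random restarts (default 5).
#' @param seed Integer seed (mandatory).
#' @param background `"input"` (0-order frequencies estimated from `seqs`,
#'   the default) or `"uniform"`.
#' @param pseudocount Per-cell pseudocount (default 0.01).
#' @param tol Convergence threshold on the max frequency change
#'   (default 1e-6); hard cap of 500 iterations.
#' @return Object of class `"motif_model"`: `width`, `counts` (width x 20
#'   expected counts), `freq` (with pseudocounts, columns sum to 1), `ic`
#'   (per-column information content in bits, relative to the background),
#'   `consensus` (degenerate positions rendered `(X/Y)`),
#'   `consensus_plain` (modal residue per column), `starts` (MAP start per
#'   sequence, 1-based), `log_likelihood`.
#' @export
discover_motif_em <- function(seqs, width, n_starts = 5L, seed,
                              background = c("input", "uniform"),
                              pseudocount = 0.01, tol = 1e-6) {
  if (missing(seed)) stop("seed is required")
  background <- match.arg(background)
  width <- as.integer(width)
  if (width < 1L) stop("width must be positive")
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  enc <- lapply(seqs, function(s) {
    ix <- match(strsplit(toupper(s), "")[[1]], .AA20)
    if (anyNA(ix)) stop("sequences must use the 20 standard residues")
    ix
  })
  lens <- lengths(enc)
  if (any(lens < width))
    stop("width ", width, " exceeds shortest sequence length ", min(lens))
  bg <- if (background == "uniform") rep(1 / 20, 20) else {
    t <- tabulate(unlist(enc), 20)
    (t + 1) / (sum(t) + 20)
  }
  log_bg <- log(bg)
  # per sequence: matrix of window residue indices (width x n_windows)
  windows <- lapply(enc, function(e) {
    nw <- length(e) - width + 1L
    vapply(seq_len(nw), function(j) e[j:(j + width - 1L)], integer(width))
  })
  # background log-likelihood of each full sequence (constant across starts)
  bg_ll <- vapply(enc, function(e) sum(log_bg[e]), numeric(1))

  run_em <- function(f) {
    ll_prev <- -Inf
    pen_prev <- -Inf
    for (iter in seq_len(500L)) {
      logf <- log(f)
      counts <- matrix(0, width, 20)
      ll <- 0
      starts <- integer(length(windows))
      for (s in seq_along(windows)) {
        W <- windows[[s]]
        # log posterior over starts: motif columns swap bg for motif freqs
        lw <- vapply(seq_len(ncol(W)), function(j)
          sum(logf[cbind(seq_len(width), W[, j])]) - sum(log_bg[W[, j]]),
          numeric(1))
        m <- max(lw)
        post <- exp(lw - m)
        post <- post / sum(post)
        ll <- ll + bg_ll[s] + m + log(mean(exp(lw - m)))
        starts[s] <- which.max(post)
        for (j in which(post > 1e-12))
          counts[cbind(seq_len(width), W[, j])] <-
            counts[cbind(seq_len(width), W[, j])] + post[j]
      }
      # MAP-EM monotonicity check on the penalized objective (log-likelihood
      # plus the Dirichlet pseudocount prior the M-step maximizes)
      pen <- ll + pseudocount * sum(log(f))
      if (pen < pen_prev - 1e-8)
        stop("internal error: EM objective decreased (", pen_prev,
             " -> ", pen, ")")
      pen_prev <- pen
      fnew <- (counts + pseudocount) / (rowSums(counts) + 20 * pseudocount)
      delta <- max(abs(fnew - f))
      f <- fnew
      ll_prev <- ll
      if (delta < tol) break
    }
    list(f = f, counts = counts, ll = ll_prev, starts = starts)
  }

  # re-seed a frequency matrix from explicit start positions
  freq_from_starts <- function(starts) {
    counts <- matrix(0, width, 20)
    for (s in seq_along(windows))
      counts[cbind(seq_len(width), windows[[s]][, starts[s]])] <-
        counts[cbind(seq_len(width), windows[[s]][, starts[s]])] + 1
    (counts + pseudocount) / (rowSums(counts) + 20 * pseudocount)
  }

  set.seed(as.integer(seed))
  best <- NULL
  for (st in seq_len(n_starts)) {
    # seed the frequency matrix from one random window, MEME-style
    s <- sample.int(length(windows), 1L)
    j <- sample.int(ncol(windows[[s]]), 1L)
    f <- matrix(rep(bg, each = width) * 0.5, width, 20)
    f[cbind(seq_len(width), windows[[s]][, j])] <-
      f[cbind(seq_len(width), windows[[s]][, j])] + 0.5
    f <- f / rowSums(f)
    r <- run_em(f)
    # phase-shift refinement: EM converges readily to an offset copy of the
    # motif; slide the MAP starts a few columns each way, re-estimate, and
    # keep the best re-converged model
    nw <- vapply(windows, ncol, integer(1))
    repeat {
      improved <- FALSE
      for (delta in setdiff(-3:3, 0L)) {
        shifted <- pmin(pmax(r$starts + delta, 1L), nw)
        rs <- run_em(freq_from_starts(shifted))
        if (rs$ll > r$ll + 1e-9) { r <- rs; improved <- TRUE }
      }
      if (!improved) break
    }
    if (is.null(best) || r$ll > best$ll) best <- r
  }

  freq <- best$f
  colnames(freq) <- .AA20
  ic <- vapply(seq_len(width), function(w) {
    p <- freq[w, ]
    sum(p * log2(p / bg))
  }, numeric(1))
  modal <- .AA20[apply(freq, 1L, which.max)]
  cons <- vapply(seq_len(width), function(w) {
    p <- sort(freq[w, ], decreasing = TRUE)
    # modal residue always shown; near-modal alternatives rendered (X/Y)
    alt <- union(names(p)[1L], names(p)[p >= max(0.2, 0.5 * p[1L])])
    if (length(alt) > 1L)
      paste0("(", paste(alt, collapse = "/"), ")") else alt
  }, character(1))
  structure(list(width = width, counts = best$counts, freq = freq, ic = ic,
                 background = bg, consensus = paste(cons, collapse = ""),
                 consensus_plain = paste(modal, collapse = ""),
                 starts = best$starts, log_likelihood = best$ll),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("ungapped motif, width ", x$width, ": ", x$consensus, "\n",
      "total IC ", round(sum(x$ic), 2), " bits; log-likelihood ",
      round(x$log_likelihood, 2), "\n", sep = "")
  invisible(x)
}

#' Logo letter heights of a motif model
#'
#' Per column, each residue's letter height is `IC * frequency`, so heights
#' sum to the column's information content.
#' @param model A `"motif_model"`.
#' @return width x 20 matrix of letter heights in bits.
#' @export
logo_heights <- function(model) model$freq * model$ic

#' Parse a degenerate motif pattern
#'
#' Patterns use one residue letter per position, `X` for any residue, and
#' square brackets or parenthesized slash-lists for alternatives:
#' `"GKGGVGK[TS]"` and `"GKGGVGK(T/S)"` are equivalent; `"GXGXXG"` is the
#' Rossmann-fold (P-loop) pattern.
#'
#' @param pattern Pattern string.
#' @return List of class `"motif_pattern"`: per-position residue sets.
#' @export
motif_pattern <- function(pattern) {
  chars <- strsplit(gsub("\\(([A-Z/]+)\\)", "[\\1]",
                         toupper(pattern)), "")[[1]]
  sets <- list(); k <- 1L
  while (k <= length(chars)) {
    ch <- chars[k]
    if (ch == "[") {
      close <- k + which(chars[(k + 1L):length(chars)] == "]")[1L]
      if (is.na(close)) stop("unclosed '[' in pattern")
      inner <- setdiff(chars[(k + 1L):(close - 1L)], "/")
      if (!length(inner)) stop("empty residue set in pattern")
      sets[[length(sets) + 1L]] <- inner
      k <- close + 1L
    } else if (ch == "X") {
      sets[[length(sets) + 1L]] <- .AA20
      k <- k + 1L
    } else if (ch %in% .AA20) {
      sets[[length(sets) + 1L]] <- ch
      k <- k + 1L
    } else stop("illegal pattern character '", ch, "'")
  }
  structure(sets, class = "motif_pattern")
}

#' Match a degenerate pattern against a protein sequence
#'
#' @param seq Protein sequence string.
#' @param pattern A [motif_pattern()] or pattern string.
#' @return Integer vector of all (possibly overlapping) 1-based start
#'   positions; empty when there is no match.
#' @export
#' @examples
#' motif_match("MGKGGVGKTA", "GKGGVGK[TS]")  # 2
motif_match <- function(seq, pattern) {
  if (is.character(pattern)) pattern <- motif_pattern(pattern)
  ch <- strsplit(toupper(seq), "")[[1]]
  w <- length(pattern)
  n <- length(ch)
  if (n < w) return(integer(0))
  hits <- integer(0)
  for (s in seq_len(n - w + 1L)) {
    ok <- TRUE
    for (k in seq_len(w)) {
      if (!ch[s + k - 1L] %in% pattern[[k]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

#' Per-group residue conservation at reference positions
#'
#' Maps reference residue positions (1-based, ungapped, e.g. the three
#' catalytic cysteines C113/C172/C422) onto alignment columns and tallies the
#' residues found there within each group of rows (typically phylogenetic
#' clusters), supporting statements like "C422 is fully conserved in
#' cluster 1 but replaced by aliphatic residues in cluster 4".
#'
#' @param msa An `"msa"` object.
#' @param ref_id Reference row id.
#' @param ref_positions Integer vector of 1-based ungapped reference positions.
#' @param group_labels Named character vector mapping every MSA row id to a
#'   group label.
#' @return Data.frame: `group`, `ref_pos`, `column` (0-based), `modal_residue`,
#'   `modal_freq` (fraction of the group's rows carrying the modal residue),
#'   `tally` (residue:count pairs, gaps as `-`).
#' @export
residue_conservation_report <- function(msa, ref_id, ref_positions,
                                        group_labels) {
  if (is.null(names(group_labels)) ||
      !all(names(msa$rows) %in% names(group_labels)))
    stop("group_labels must name every MSA row")
  unknown <- setdiff(names(group_labels), names(msa$rows))
  if (length(unknown))
    stop("unknown row in group_labels: ", unknown[1L])
  cols <- vapply(ref_positions, function(p)
    map_reference_column(msa, ref_id, p), integer(1))
  chars <- lapply(msa$rows, function(r) strsplit(r, "")[[1]])
  groups <- split(names(msa$rows), group_labels[names(msa$rows)])
  if (any(lengths(groups) == 0L)) stop("empty group")
  out <- list()
  for (g in names(groups)) {
    for (k in seq_along(ref_positions)) {
      res <- vapply(chars[groups[[g]]], `[`, character(1), cols[k] + 1L)
      t <- sort(table(res), decreasing = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        group = g, ref_pos = ref_positions[k], column = cols[k],
        modal_residue = names(t)[1L],
        modal_freq = as.numeric(t[1L]) / length(res),
        tally = paste(sprintf("%s:%d", names(t), as.integer(t)),
                      collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
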