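# Kyte & Doolittle (1982) residue hydropathy scale
.KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

kd_values <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  v <- .KD_SCALE[ch]
  if (anyNA(v)) stop("illegal residue '", ch[which(is.na(v))[1L]], "'")
  unname(v)
}

#' Sliding-window Kyte-Doolittle hydropathy profile
#'
#' Centered moving average of per-residue hydropathy values over an odd
#' window (default 19, the standard setting for transmembrane-helix scans).
#' Positions closer than `window %/% 2` to either end carry `NA`.
#'
#' @param seq Protein sequence (length at least `window`).
#' @param window Odd positive window size (default 19).
#' @return Numeric vector as long as the sequence.
#' @export
kyte_doolittle_profile <- function(seq, window = 19L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd positive")
  v <- kd_values(seq)
  n <- length(v)
  if (n < window)
    stop("sequence length ", n, " shorter than window ", window)
  half <- window %/% 2L
  cs <- cumsum(c(0, v))
  out <- rep(NA_real_, n)
  centers <- seq(half + 1L, n - half)
  out[centers] <- (cs[centers + half + 1L] - cs[centers - half]) / window
  out
}

hydrophobic_moment <- function(v, angle_deg = 100) {
  th <- angle_deg * pi / 180 * seq_along(v)
  sqrt(sum(v * sin(th))^2 + sum(v * cos(th))^2) / length(v)
}

moment_profile <- function(seq, window = 19L, angle_deg = 100) {
  v <- kd_values(seq)
  n <- length(v)
  half <- window %/% 2L
  out <- rep(NA_real_, n)
  if (n < window) return(out)
  for (c in seq(half + 1L, n - half))
    out[c] <- hydrophobic_moment(v[(c - half):(c + half)], angle_deg)
  out
}

#' Alignment-averaged hydropathy, amphipathicity, and similarity profiles
#'
#' Per alignment column: mean sliding-window hydropathy over the rows that
#' carry a residue there, mean hydrophobic moment at 100 degrees per helical
#' turn (alpha-helical amphipathicity) over the same window, and a similarity
#' score equal to the frequency of the column's modal residue. Row profiles
#' are computed on the ungapped sequences and mapped back onto columns;
#' all-gap columns carry `NA`.
#'
#' @param msa An `"msa"` object with at least 2 rows.
#' @param window Odd window size (default 19).
#' @param angle_deg Helical periodicity for the moment (default 100).
#' @return Data.frame with one row per alignment column: `column` (0-based),
#'   `hydropathy`, `amphipathicity`, `similarity`.
#' @export
average_profiles <- function(msa, window = 19L, angle_deg = 100) {
  rows <- msa$rows
  if (length(rows) < 2L) stop("need an alignment of at least 2 rows")
  L <- msa$ncol
  hyd <- amp <- matrix(NA_real_, length(rows), L)
  chars <- matrix("-", length(rows), L)
  for (r in seq_along(rows)) {
    ch <- strsplit(rows[[r]], "")[[1]]
    chars[r, ] <- ch
    nong <- which(ch != "-")
    s <- paste(ch[nong], collapse = "")
    if (nchar(s) >= window) {
      hyd[r, nong] <- kyte_doolittle_profile(s, window)
      amp[r, nong] <- moment_profile(s, window, angle_deg)
    }
  }
  sim <- vapply(seq_len(L), function(c) {
    col <- chars[, c]
    col <- col[col != "-"]
    if (!length(col)) return(NA_real_)
    max(table(col)) / length(col)
  }, numeric(1))
  data.frame(
    column = seq_len(L) - 1L,
    hydropathy = colMeans(hyd, na.rm = TRUE),
    amphipathicity = colMeans(amp, na.rm = TRUE),
    similarity = sim
  )
}

#' Call transmembrane segments from a hydropathy profile
#'
#' Maximal runs of profile positions above `threshold` of length at least
#' `min_len`; runs separated by fewer than `merge_gap` positions are merged
#' before the length filter. Defaults (1.6 / 15) follow common practice for
#' Kyte-Doolittle window-19 profiles.
#'
#' @param profile Numeric vector from [kyte_doolittle_profile()] (`NA`s at
#'   the ends are treated as below threshold).
#' @param threshold Hydropathy threshold (default 1.6).
#' @param min_len Minimum segment length (default 15).
#' @param merge_gap Merge runs separated by fewer than this many positions
#'   (default 4).
#' @return Data.frame with columns `start`, `end` (1-based inclusive).
#' @export
predict_tms <- function(profile, threshold = 1.6, min_len = 15L,
                        merge_gap = 4L) {
  above <- !is.na(profile) & profile > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values], ends[r$values])
  if (!is.matrix(iv)) iv <- matrix(iv, ncol = 2L)
  if (nrow(iv) > 1L) {
    merged <- iv[1L, , drop = FALSE]
    for (k in 2L:nrow(iv)) {
      if (iv[k, 1L] - merged[nrow(merged), 2L] - 1L < merge_gap)
        merged[nrow(merged), 2L] <- iv[k, 2L]
      else merged <- rbind(merged, iv[k, ])
    }
    iv <- merged
  }
  iv <- iv[iv[, 2L] - iv[, 1L] + 1L >= min_len, , drop = FALSE]
  data.frame(start = iv[, 1L], end = iv[, 2L])
}
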