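# 1/f detrending and spectral peak detection shared by the IAF estimator and
# the ratio-conformity fit.

# Straight-line fit of log(power) on log(frequency) over the full PSD
# support, subtracted: the simplest aperiodic (1/f) model. Zero-power samples
# cannot enter the fit; their detrended value is set to -Inf so they can
# never be peaks.
detrend_loglog <- function(psd) {
  stopifnot(inherits(psd, "psd_table"))
  logf <- log(psd$freqs)
  pos <- psd$power > 0
  if (sum(pos) < 2L) {
    stop("PSD has fewer than two positive power samples; cannot detrend",
         call. = FALSE)
  }
  fit <- stats::lm(log(psd$power[pos]) ~ logf[pos])
  co <- stats::coef(fit)
  detrended <- rep(-Inf, length(psd$freqs))
  detrended[pos] <- log(psd$power[pos]) - (co[[1]] + co[[2]] * logf[pos])
  list(logf = logf, detrended = detrended,
       intercept = co[[1]], slope = co[[2]])
}

# Topographic prominence of a local maximum at index i of series d: height
# above the higher of the two valley floors separating it from higher ground
# (or from the series edge).
peak_prominence <- function(d, i) {
  n <- length(d)
  left_min <- d[i]
  j <- i - 1L
  while (j >= 1L && d[j] <= d[i]) {
    left_min <- min(left_min, d[j])
    j <- j - 1L
  }
  if (j < 1L) left_min <- min(d[seq_len(i)])
  right_min <- d[i]
  j <- i + 1L
  while (j <= n && d[j] <= d[i]) {
    right_min <- min(right_min, d[j])
    j <- j + 1L
  }
  if (j > n) right_min <- min(d[i:n])
  d[i] - max(left_min, right_min)
}

# Sub-bin peak localization: vertex of the quadratic through the three
# samples around a local maximum, in log-frequency coordinates (a Gaussian
# peak on a log grid is locally parabolic). Falls back to the grid sample
# when the neighbors are unusable; the vertex is clamped to the neighbor
# interval.
refine_peak_freq <- function(logf, d, i) {
  if (i <= 1L || i >= length(d)) return(exp(logf[i]))
  x <- logf[(i - 1L):(i + 1L)]
  y <- d[(i - 1L):(i + 1L)]
  if (any(!is.finite(y))) return(exp(logf[i]))
  # exact quadratic through three points
  co <- solve(cbind(1, x, x^2), y)
  if (co[3] >= 0) return(exp(logf[i]))
  v <- -co[2] / (2 * co[3])
  exp(min(max(v, x[1]), x[3]))
}

# Approximate peak width: frequency span where the detrended series stays
# above height - prominence/2, linearly interpolated; clamped at grid edges.
peak_width <- function(freqs, d, i, prom) {
  half <- d[i] - prom / 2
  lo <- freqs[i]
  for (j in seq(i, 2L)) {
    if (d[j - 1L] < half) {
      lo <- freqs[j - 1L] + (freqs[j] - freqs[j - 1L]) *
        (half - d[j - 1L]) / (d[j] - d[j - 1L])
      break
    }
    lo <- freqs[j - 1L]
  }
  hi <- freqs[i]
  n <- length(d)
  if (i < n) {
    for (j in seq(i, n - 1L)) {
      if (d[j + 1L] < half) {
        hi <- freqs[j] + (freqs[j + 1L] - freqs[j]) *
          (d[j] - half) / (d[j] - d[j + 1L])
        break
      }
      hi <- freqs[j + 1L]
    }
  }
  hi - lo
}

#' Detect spectral peaks on the 1/f-detrended spectrum
#'
#' Fits a straight line to log-power versus log-frequency over the whole PSD
#' support (the aperiodic component), subtracts it, and reports the local
#' maxima of the residual that rise above the fitted baseline. Peak
#' frequencies are refined to sub-bin precision by quadratic interpolation of
#' the three samples around each maximum in log-frequency coordinates. Peaks
#' are returned sorted by descending prominence (ties by ascending
#' frequency).
#'
#' @param psd A [psd_table()].
#' @param f_range Optional `c(lo, hi)` restriction in Hz; peaks are searched
#'   within it while the detrend always uses the full support.
#' @param min_prominence Minimum topographic prominence in detrended
#'   log-power units; candidates below it are dropped.
#' @param max_peaks Keep at most this many peaks.
#' @return An object of class `peak_set`: data frame with `frequency` (Hz),
#'   `height` (detrended log-power at the peak), `prominence` and `width`
#'   (approximate half-prominence width in Hz). Zero rows when nothing
#'   qualifies.
#' @export
find_spectral_peaks <- function(psd, f_range = NULL, min_prominence = 0,
                                max_peaks = Inf) {
  det <- detrend_loglog(psd)
  d <- det$detrended
  n <- length(d)
  idx <- which(d[seq(2, n - 1L)] > d[seq(1, n - 2L)] &
                 d[seq(2, n - 1L)] > d[seq(3, n)]) + 1L
  # only maxima above the fitted aperiodic baseline count as peaks
  idx <- idx[d[idx] > 0]
  if (!is.null(f_range)) {
    stopifnot(length(f_range) == 2L, f_range[1] < f_range[2])
    idx <- idx[psd$freqs[idx] >= f_range[1] & psd$freqs[idx] <= f_range[2]]
  }
  prom <- vapply(idx, function(i) peak_prominence(d, i), numeric(1))
  keep <- prom >= min_prominence
  idx <- idx[keep]
  prom <- prom[keep]
  # descending prominence; ties (within 1e-9) broken toward lower frequency
  ord <- order(-round(prom / 1e-9) * 1e-9, psd$freqs[idx])
  idx <- idx[ord]
  prom <- prom[ord]
  if (is.finite(max_peaks) && length(idx) > max_peaks) {
    idx <- idx[seq_len(max_peaks)]
    prom <- prom[seq_len(max_peaks)]
  }
  width <- vapply(seq_along(idx), function(k) {
    peak_width(psd$freqs, d, idx[k], prom[k])
  }, numeric(1))
  freq <- vapply(idx, function(i) refine_peak_freq(det$logf, d, i), numeric(1))
  structure(
    data.frame(frequency = freq, height = d[idx],
               prominence = prom, width = width),
    class = c("peak_set", "data.frame")
  )
}
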