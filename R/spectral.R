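# Applying a band scheme to spectra: classification, band power, scheme
# comparison, environmental-mode alignment, and the geometric-ratio
# conformity fit.

#' Classify frequencies into scheme bands
#'
#' Bands are lower-closed/upper-open `[lower, upper)`, so a frequency equal
#' to a shared boundary belongs to the upper band (10.5 Hz classifies as
#' alpha2 in the default scheme). Frequencies outside the scheme's coverage
#' (possible only for schemes without open ends, such as the traditional
#' preset) return `NA`.
#'
#' @param f Frequencies in Hz, positive; vectorized.
#' @param scheme A [band_scheme()].
#' @return Character vector of band labels.
#' @examples
#' classify_frequency(c(9, 10.5, 25), tbb_scheme())
#' @export
classify_frequency <- function(f, scheme) {
  check_positive_vector(f, "f")
  validate_band_scheme(scheme)
  b <- scheme$bands
  idx <- findInterval(f, b$lower)
  out <- rep(NA_character_, length(f))
  ok <- idx >= 1L & idx <= nrow(b)
  ok[ok] <- f[ok] < b$upper[idx[ok]]
  out[ok] <- b$label[idx[ok]]
  out
}

# trapezoidal integral of the piecewise-linear PSD over [a, b], with the
# endpoints interpolated onto the grid (exact for trapezoid-consistent
# spectra)
trapz_between <- function(freqs, power, a, b) {
  a <- max(a, freqs[1])
  b <- min(b, freqs[length(freqs)])
  if (a >= b) return(0)
  inner <- freqs > a & freqs < b
  xs <- c(a, freqs[inner], b)
  ys <- c(stats::approx(freqs, power, xout = a)$y,
          power[inner],
          stats::approx(freqs, power, xout = b)$y)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Band power of a PSD under a scheme
#'
#' Integrates the PSD over each band interval by the trapezoidal rule, with
#' linear interpolation of the density at band boundaries so that adjacent
#' bands split boundary bins exactly. Open-ended bands are truncated at the
#' PSD grid limits (and optionally at `f_max_cap`). Relative power is each
#' band's share of the total over the covered support, so relative powers sum
#' to 1.
#'
#' @param psd A [psd_table()].
#' @param scheme A [band_scheme()].
#' @param f_max_cap Optional upper truncation frequency in Hz.
#' @return A data frame of class `band_power` with `label`, `lower`, `upper`
#'   (the integration limits actually used), `absolute_power` and
#'   `relative_power`.
#' @examples
#' flat <- psd_table(seq(1, 40, by = 0.5), rep(1, 79))
#' band_power(flat, tbb_scheme())
#' @export
band_power <- function(psd, scheme, f_max_cap = NULL) {
  stopifnot(inherits(psd, "psd_table"))
  validate_band_scheme(scheme)
  b <- scheme$bands
  f1 <- psd$freqs[1]
  f2 <- psd$freqs[length(psd$freqs)]
  if (!is.null(f_max_cap)) {
    check_positive_scalar(f_max_cap, "f_max_cap")
    f2 <- min(f2, f_max_cap)
  }
  lo <- pmax(b$lower, f1)
  hi <- pmin(b$upper, f2)
  if (all(lo >= hi)) {
    stop("PSD support does not overlap any band of the scheme", call. = FALSE)
  }
  absolute <- vapply(seq_len(nrow(b)), function(i) {
    trapz_between(psd$freqs, psd$power, lo[i], hi[i])
  }, numeric(1))
  total <- sum(absolute)
  if (total <= 0) {
    stop("total power over the covered support is zero; relative powers undefined",
         call. = FALSE)
  }
  structure(
    data.frame(label = b$label, lower = lo, upper = hi,
               absolute_power = absolute, relative_power = absolute / total,
               stringsAsFactors = FALSE),
    class = c("band_power", "data.frame")
  )
}

#' Band power under two schemes, side by side
#'
#' Runs [band_power()] under both schemes and pairs the rows by band label.
#' Matched labels get the relative-power difference (`a - b`); labels present
#' in only one scheme are reported one-sided with `NA` in the other columns.
#'
#' @param psd A [psd_table()].
#' @param scheme_a,scheme_b Two [band_scheme()] objects.
#' @param names Length-2 suffixes for the two schemes' columns.
#' @return Data frame with per-label absolute and relative powers under both
#'   schemes and `relative_diff`.
#' @export
compare_schemes <- function(psd, scheme_a, scheme_b, names = c("a", "b")) {
  stopifnot(length(names) == 2L)
  pa <- band_power(psd, scheme_a)
  pb <- band_power(psd, scheme_b)
  da <- pa[, c("label", "absolute_power", "relative_power")]
  db <- pb[, c("label", "absolute_power", "relative_power")]
  names(da)[2:3] <- paste(c("absolute", "relative"), names[1], sep = "_")
  names(db)[2:3] <- paste(c("absolute", "relative"), names[2], sep = "_")
  out <- merge(da, db, by = "label", all = TRUE, sort = FALSE)
  out$relative_diff <- out[[paste0("relative_", names[1])]] -
    out[[paste0("relative_", names[2])]]
  # keep a stable order: scheme_a's bands first, then b-only labels
  ord <- c(match(pa$label, out$label),
           setdiff(seq_len(nrow(out)), match(pa$label, out$label)))
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Alignment of scheme features with environmental reference modes
#'
#' For each reference mode (defaults: the 7.83 Hz fundamental Schumann
#' resonance and its harmonics near 14.1, 20.3, 26 and 33 Hz) finds the
#' nearest scheme feature -- any band center or closed boundary -- and the
#' percent deviation `100 * |feature - mode| / mode`. The deviation of the
#' theta/alpha boundary from the first mode is reported as a named headline,
#' since that is the scheme's flagship correspondence.
#'
#' @param scheme A [band_scheme()].
#' @param modes Positive reference frequencies in Hz.
#' @return An object of class `alignment_report`: list with `table` (one row
#'   per mode: `mode_freq`, `feature_kind`, `feature_label`, `feature_freq`,
#'   `percent_deviation`) and `headline` (theta/alpha boundary vs the first
#'   mode, `NA` if the scheme has no theta band).
#' @examples
#' schumann_alignment(tbb_scheme())
#' @export
schumann_alignment <- function(scheme,
                               modes = c(7.83, 14.1, 20.3, 26.0, 33.0)) {
  validate_band_scheme(scheme)
  if (length(modes) < 1L) stop("`modes` must not be empty", call. = FALSE)
  check_positive_vector(modes, "modes")
  feats <- scheme_features(scheme)
  rows <- lapply(modes, function(m) {
    dev <- 100 * abs(feats$freq - m) / m
    i <- which.min(dev)
    data.frame(mode_freq = m, feature_kind = feats$kind[i],
               feature_label = feats$label[i], feature_freq = feats$freq[i],
               percent_deviation = dev[i], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)

  b <- scheme$bands
  i_theta <- match("theta", b$label)
  headline <- if (!is.na(i_theta) && i_theta < nrow(b)) {
    bd <- b$upper[i_theta]
    list(boundary_label = paste0("theta/", b$label[i_theta + 1L]),
         boundary_freq = bd, mode_freq = modes[1],
         percent_deviation = 100 * abs(bd - modes[1]) / modes[1])
  } else {
    list(boundary_label = NA_character_, boundary_freq = NA_real_,
         mode_freq = modes[1], percent_deviation = NA_real_)
  }
  structure(list(table = tab, headline = headline), class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, digits = 3, ...) {
  cat("Alignment with environmental reference modes\n")
  tab <- x$table
  tab$feature_freq <- round(tab$feature_freq, digits)
  tab$percent_deviation <- round(tab$percent_deviation, digits)
  print(tab, row.names = FALSE, ...)
  h <- x$headline
  if (!is.na(h$percent_deviation)) {
    cat(sprintf("headline: %s boundary %.4g Hz vs %.4g Hz mode -> %.3f%% deviation\n",
                h$boundary_label, h$boundary_freq, h$mode_freq,
                h$percent_deviation))
  }
  invisible(x)
}

#' @export
as.data.frame.alignment_report <- function(x, ...) x$table

#' Deviation of the classical Titius-Bode theta center from a reference mode
#'
#' Signed percentage `100 * (mode - theta_center) / mode`, positive when the
#' classical theta center (0.7 * f_ref) lies below the mode. For the default
#' anchor 10.5 Hz and the 7.83 Hz fundamental this is about 6%.
#'
#' @param f_ref Anchor frequency in Hz (alpha center).
#' @param mode Reference mode frequency in Hz.
#' @return Signed percentage.
#' @examples
#' classical_deviation(10.5)
#' @export
classical_deviation <- function(f_ref, mode = 7.83) {
  check_positive_scalar(f_ref, "f_ref")
  check_positive_scalar(mode, "mode")
  theta <- classical_tb_centers(f_ref)
  th <- theta$center[theta$label == "theta"]
  100 * (mode - th) / mode
}

#' Fit the geometric scaling ratio to observed spectral peaks
#'
#' Conformity of a spectrum to the geometric band hierarchy: each peak is
#' assigned a candidate integer index by rounding [index_of()] under a trial
#' anchor, and `log f = log f_ref + n log R` is fit by least squares for each
#' distinct assignment. Trial anchors are 64 log-spaced candidates between
#' `min(peaks) / R_init` and `max(peaks)` (bounded, deterministic search).
#' The assignment minimizing the RMS log-residual wins; `R_hat` is the
#' exponential of the fitted slope.
#'
#' @param peaks Numeric vector of peak frequencies in Hz, or a `peak_set`
#'   from [find_spectral_peaks()]. At least two distinct frequencies.
#' @param R_init Initial ratio used for index assignment (default 1.7275).
#' @param n_ref_candidates Number of trial anchors (default 64).
#' @return An object of class `ratio_fit`: list with `R_hat`, `f_ref_hat`,
#'   `residual_rms` (log-Hz units), and `index_assignment` (named integer
#'   vector, peak frequency -> index).
#' @examples
#' estimate_geometric_ratio(10.5 * 1.7275^(-2:2))
#' @export
estimate_geometric_ratio <- function(peaks, R_init = 1.7275,
                                     n_ref_candidates = 64L) {
  if (inherits(peaks, "peak_set")) peaks <- peaks$frequency
  check_positive_vector(peaks, "peaks")
  check_positive_scalar(R_init, "R_init")
  if (R_init <= 1) stop("`R_init` must exceed 1", call. = FALSE)
  f <- sort(unique(peaks))
  if (length(f) < 2L) {
    stop("need at least 2 distinct peak frequencies to fit a ratio",
         call. = FALSE)
  }
  cand <- exp(seq(log(min(f) / R_init), log(max(f)),
                  length.out = n_ref_candidates))
  logf <- log(f)
  seen <- character(0)
  best <- NULL
  for (fr in cand) {
    n <- round(index_of(f, fr, R_init))
    if (length(unique(n)) < 2L) next
    key <- paste(n, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    fit <- stats::lm(logf ~ n)
    slope <- stats::coef(fit)[[2]]
    if (slope <= 0) next
    rms <- sqrt(mean(stats::residuals(fit)^2))
    if (is.null(best) || rms < best$residual_rms) {
      best <- list(
        R_hat = exp(slope),
        f_ref_hat = exp(stats::coef(fit)[[1]]),
        residual_rms = rms,
        index_assignment = stats::setNames(as.integer(n), format(f))
      )
    }
  }
  if (is.null(best)) {
    stop("degenerate peak set: no anchor candidate separates the peaks into distinct indices",
         call. = FALSE)
  }
  structure(best, class = "ratio_fit")
}

#' @export
print.ratio_fit <- function(x, ...) {
  cat(sprintf("Geometric ratio fit: R_hat = %.5f, f_ref_hat = %.4g Hz, RMS log-residual = %.3g\n",
              x$R_hat, x$f_ref_hat, x$residual_rms))
  cat("indices:", paste(names(x$index_assignment), x$index_assignment,
                        sep = " -> ", collapse = ", "), "\n")
  invisible(x)
}
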