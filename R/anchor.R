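# Candidate reference (anchor) frequencies for a geometric scheme: analytic
# heuristics from the spectrum edges, and the data-driven individual alpha
# frequency (IAF).

#' Bundle an anchor candidate with its provenance
#'
#' @param value Anchor frequency in Hz, positive.
#' @param method One of `"fixed"`, `"edge_geometric_mean"`, `"golden_ratio"`,
#'   `"iaf_peak"`.
#' @param search_window `c(lo, hi)` in Hz for data-driven methods, else `NULL`.
#' @param quality Peak prominence in detrended log-power units for data-driven
#'   methods; 0 for analytic ones.
#' @return An object of class `anchor_estimate`.
#' @export
anchor_estimate <- function(value,
                            method = c("fixed", "edge_geometric_mean",
                                       "golden_ratio", "iaf_peak"),
                            search_window = NULL, quality = 0) {
  method <- match.arg(method)
  check_positive_scalar(value, "value")
  if (!is.null(search_window)) {
    stopifnot(length(search_window) == 2L, search_window[1] < search_window[2])
    if (value < search_window[1] || value > search_window[2]) {
      stop("anchor value falls outside its search window", call. = FALSE)
    }
  }
  structure(list(value = value, method = method,
                 search_window = search_window, quality = quality),
            class = "anchor_estimate")
}

#' @export
print.anchor_estimate <- function(x, ...) {
  cat(sprintf("Anchor estimate: %.4g Hz (%s%s)\n", x$value, x$method,
              if (x$method == "iaf_peak")
                sprintf(", window %g-%g Hz, prominence %.3g",
                        x$search_window[1], x$search_window[2], x$quality)
              else ""))
  invisible(x)
}

#' Geometric mean of the spectrum edges
#'
#' The logarithmic center of an analysis range, e.g. sqrt(0.5 * 100) ~ 7.07 Hz
#' for the conventional 0.5-100 Hz EEG span. A simple analytic anchor
#' candidate.
#'
#' @param f_low,f_high Lower and upper edge of the spectrum in Hz,
#'   `0 < f_low <= f_high`.
#' @return Frequency in Hz.
#' @examples
#' edge_geometric_mean(0.5, 100)
#' @export
edge_geometric_mean <- function(f_low, f_high) {
  check_positive_scalar(f_low, "f_low")
  check_positive_scalar(f_high, "f_high")
  if (f_low > f_high) stop("`f_low` must not exceed `f_high`", call. = FALSE)
  sqrt(f_low * f_high)
}

#' Golden-ratio-scaled spectrum-edge anchor
#'
#' The edge geometric mean scaled by the golden ratio phi: for the 0.5-100 Hz
#' span this yields ~11.4 Hz, close to the 10.5 Hz adult alpha mean used as
#' the default anchor.
#'
#' @inheritParams edge_geometric_mean
#' @param phi Scaling factor; defaults to the golden ratio (1 + sqrt(5)) / 2.
#' @return Frequency in Hz.
#' @examples
#' golden_ratio_reference(0.5, 100)
#' @export
golden_ratio_reference <- function(f_low, f_high, phi = (1 + sqrt(5)) / 2) {
  check_positive_scalar(phi, "phi")
  edge_geometric_mean(f_low, f_high) * phi
}

#' Estimate the individual alpha frequency from a PSD
#'
#' Removes the aperiodic 1/f trend (straight-line fit of log-power on
#' log-frequency over the full support) and returns the frequency of the most
#' prominent residual local maximum within the search window. Equally
#' prominent peaks resolve to the lower frequency. When no local maximum
#' rises above the detrended baseline inside the window, a classed
#' `geobands_no_peak` error is raised rather than any silent default.
#'
#' @param psd A [psd_table()] whose grid covers the window with at least 5
#'   samples.
#' @param window `c(lo, hi)` search window in Hz; the default 7-14 Hz
#'   brackets both the classical alpha range and the geometric scheme's
#'   alpha1/alpha2 span.
#' @return An [anchor_estimate()] with `method = "iaf_peak"` and `quality`
#'   set to the peak prominence.
#' @export
estimate_iaf <- function(psd, window = c(7, 14)) {
  stopifnot(inherits(psd, "psd_table"), length(window) == 2L,
            window[1] < window[2])
  n_in <- sum(psd$freqs >= window[1] & psd$freqs <= window[2])
  if (n_in < 5L) {
    stop("PSD grid must cover the search window with at least 5 samples",
         call. = FALSE)
  }
  peaks <- find_spectral_peaks(psd, f_range = window)
  if (nrow(peaks) == 0L) {
    stop(errorCondition(
      sprintf("no spectral peak above the 1/f baseline in %g-%g Hz",
              window[1], window[2]),
      class = c("geobands_no_peak", "error", "condition")
    ))
  }
  anchor_estimate(peaks$frequency[1], method = "iaf_peak",
                  search_window = window, quality = peaks$prominence[1])
}
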