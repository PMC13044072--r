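#' Power spectral density table
#'
#' Container for a sampled one-sided power spectral density: a strictly
#' increasing frequency grid and nonnegative power-density values in
#' arbitrary consistent units (e.g. uV^2/Hz).
#'
#' @param freqs Frequencies in Hz, strictly increasing, all positive.
#' @param power Power density values, same length, all `>= 0` and finite.
#' @param meta Optional named list of free-form provenance labels.
#' @return An object of class `psd_table` (a list with `freqs`, `power`,
#'   `meta`).
#' @examples
#' psd_table(1:40, rep(1, 40))
#' @export
psd_table <- function(freqs, power, meta = list()) {
  if (!is.numeric(freqs) || !is.numeric(power)) {
    stop("`freqs` and `power` must be numeric", call. = FALSE)
  }
  if (length(freqs) != length(power)) {
    stop("`freqs` and `power` must have the same length", call. = FALSE)
  }
  if (length(freqs) < 2L) stop("a PSD needs at least two samples", call. = FALSE)
  if (any(!is.finite(freqs)) || any(freqs <= 0)) {
    stop("frequencies must be positive and finite", call. = FALSE)
  }
  if (any(diff(freqs) <= 0)) {
    stop("frequency grid must be strictly increasing", call. = FALSE)
  }
  bad <- which(!is.finite(power) | power < 0)
  if (length(bad)) {
    stop(sprintf("power must be nonnegative and finite (first offending sample: %d)",
                 bad[1]), call. = FALSE)
  }
  structure(list(freqs = as.numeric(freqs), power = as.numeric(power),
                 meta = meta),
            class = "psd_table")
}

#' @export
print.psd_table <- function(x, ...) {
  cat(sprintf("PSD: %d samples, %.3g-%.3g Hz (step ~%.3g Hz)\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              stats::median(diff(x$freqs))))
  if (length(x$meta)) {
    cat("meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                       sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.psd_table <- function(x, ...) {
  data.frame(frequency_hz = x$freqs, power = x$power)
}

#' Read a PSD from a two-column CSV file
#'
#' Expects a comma-separated file with a one-line header and two numeric
#' columns: frequency in Hz and power density (the canonical header is
#' `frequency_hz,power`, but any two-column numeric file with a header is
#' accepted). The grid must be strictly increasing and the power nonnegative;
#' violations are reported with the offending data row.
#'
#' @param path File path.
#' @return A [psd_table()].
#' @export
read_psd_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, header = TRUE)
  if (ncol(df) < 2L) stop("PSD CSV needs two columns (frequency, power)", call. = FALSE)
  freqs <- suppressWarnings(as.numeric(df[[1]]))
  power <- suppressWarnings(as.numeric(df[[2]]))
  bad <- which(!is.finite(freqs) | !is.finite(power))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric or missing value at data row %d", path, bad[1]),
         call. = FALSE)
  }
  if (any(diff(freqs) <= 0)) {
    stop(sprintf("%s: frequency grid not strictly increasing at data row %d",
                 path, which(diff(freqs) <= 0)[1] + 1L), call. = FALSE)
  }
  if (any(power < 0)) {
    stop(sprintf("%s: negative power at data row %d", path, which(power < 0)[1]),
         call. = FALSE)
  }
  psd_table(freqs, power, meta = list(source = path))
}

#' Write a PSD to CSV
#'
#' Writes the canonical two-column dialect (`frequency_hz,power`, UTF-8,
#' "." decimal separator) read back by [read_psd_csv()].
#'
#' @param psd A [psd_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psd_csv <- function(psd, path) {
  stopifnot(inherits(psd, "psd_table"))
  utils::write.csv(as.data.frame(psd), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
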