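# Seeded synthetic spectra and time series with known ground truth, so every
# analysis operation is testable without recorded data.

#' Specification of a synthetic EEG-like spectrum
#'
#' Describes a PSD as a 1/f (aperiodic) background `background_amp * f^-beta`
#' plus Gaussian oscillatory peaks, observed under multiplicative log-normal
#' noise. Defaults emulate a resting adult EEG spectrum: 1-45 Hz at 0.5 Hz
#' resolution (the grid a 2-s-segment Welch estimate would give), aperiodic
#' exponent 1, and mild (sd 0.05 log units) across-frequency noise.
#'
#' @param background_amp Aperiodic amplitude in density units at 1 Hz.
#' @param background_exp Aperiodic exponent beta (power ~ f^-beta), >= 0.
#' @param peaks `NULL` or a data frame with columns `center` (Hz),
#'   `amplitude` (density units, >= 0) and `sd` (Hz, > 0).
#' @param noise_sd Standard deviation of the multiplicative log-normal noise
#'   in log units; 0 for a noiseless spectrum.
#' @param f_min,f_max,n_points Frequency grid: `f_min > 0`, `n_points >= 8`.
#' @param seed Integer seed; the same spec always yields bit-identical data.
#' @return An object of class `synth_spec`.
#' @examples
#' synth_spec(peaks = data.frame(center = 10.2, amplitude = 2, sd = 1))
#' @export
synth_spec <- function(background_amp = 1, background_exp = 1, peaks = NULL,
                       noise_sd = 0.05, f_min = 1, f_max = 45,
                       n_points = 89L, seed = 1L) {
  stopifnot(is.numeric(background_amp), length(background_amp) == 1L,
            is.finite(background_amp), background_amp >= 0)
  stopifnot(is.numeric(background_exp), length(background_exp) == 1L,
            background_exp >= 0)
  stopifnot(is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0)
  check_positive_scalar(f_min, "f_min")
  check_positive_scalar(f_max, "f_max")
  if (f_min >= f_max) stop("`f_min` must be below `f_max`", call. = FALSE)
  if (n_points < 8L) stop("`n_points` must be at least 8", call. = FALSE)
  stopifnot(length(seed) == 1L, is.finite(seed), seed == round(seed))
  if (is.null(peaks)) {
    peaks <- data.frame(center = numeric(0), amplitude = numeric(0),
                        sd = numeric(0))
  }
  stopifnot(is.data.frame(peaks),
            all(c("center", "amplitude", "sd") %in% names(peaks)))
  if (nrow(peaks)) {
    check_positive_vector(peaks$center, "peaks$center")
    check_positive_vector(peaks$sd, "peaks$sd")
    stopifnot(all(peaks$amplitude >= 0))
  }
  structure(
    list(background_amp = background_amp, background_exp = background_exp,
         peaks = peaks, noise_sd = noise_sd,
         f_min = f_min, f_max = f_max, n_points = as.integer(n_points),
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# noiseless model PSD evaluated on a frequency grid
synth_model_power <- function(spec, freqs) {
  power <- spec$background_amp * freqs^(-spec$background_exp)
  if (nrow(spec$peaks)) {
    for (i in seq_len(nrow(spec$peaks))) {
      p <- spec$peaks[i, ]
      power <- power + p$amplitude * exp(-(freqs - p$center)^2 / (2 * p$sd^2))
    }
  }
  power
}

#' Generate a synthetic PSD
#'
#' Evaluates the spec's 1/f-plus-Gaussian-peaks model on its frequency grid
#' and multiplies by seeded log-normal noise (multiplicative, so the PSD
#' stays positive). Deterministic for a fixed spec.
#'
#' @param spec A [synth_spec()].
#' @return A [psd_table()]; the spec travels along in `meta$spec` as ground
#'   truth.
#' @export
synth_psd <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  freqs <- seq(spec$f_min, spec$f_max, length.out = spec$n_points)
  power <- synth_model_power(spec, freqs)
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(spec$seed,
                              stats::rnorm(spec$n_points, 0, spec$noise_sd))
    power <- power * exp(noise)
  }
  psd_table(freqs, power, meta = list(spec = spec))
}

#' Generate a synthetic time series matching a spectral spec
#'
#' Sum of sinusoids at the spec's peak centers (seeded random phases,
#' amplitudes chosen so each sinusoid carries the power integral of its
#' Gaussian PSD peak) plus 1/f-shaped noise synthesized by spectral shaping
#' of white noise, so the target aperiodic slope is exact in expectation.
#'
#' @param spec A [synth_spec()].
#' @param fs Sampling rate in Hz; must exceed twice the highest peak center.
#' @param duration Length in seconds, at least 4.
#' @return Numeric vector of `fs * duration` samples with attribute `fs`.
#' @export
synth_timeseries <- function(spec, fs, duration) {
  stopifnot(inherits(spec, "synth_spec"))
  check_positive_scalar(fs, "fs")
  stopifnot(is.numeric(duration), length(duration) == 1L, duration >= 4)
  if (nrow(spec$peaks) && fs <= 2 * max(spec$peaks$center)) {
    stop("sampling rate violates the Nyquist criterion for the highest peak",
         call. = FALSE)
  }
  n <- round(fs * duration)
  t <- seq(0, by = 1 / fs, length.out = n)
  x <- withr::with_seed(spec$seed, {
    x <- numeric(n)
    if (nrow(spec$peaks)) {
      for (i in seq_len(nrow(spec$peaks))) {
        p <- spec$peaks[i, ]
        # Gaussian peak area = sinusoid power a^2/2
        area <- p$amplitude * p$sd * sqrt(2 * pi)
        a <- sqrt(2 * area)
        x <- x + a * sin(2 * pi * p$center * t + stats::runif(1, 0, 2 * pi))
      }
    }
    if (spec$background_amp > 0) {
      half <- floor(n / 2)
      fk <- (1:half) * fs / n
      s <- spec$background_amp * fk^(-spec$background_exp)
      # complex spectrum with E|X_k|^2 = S_k * fs * n / 2 so the one-sided
      # periodogram of the synthesized noise matches the target density
      mag <- sqrt(s * fs * n / 4)
      xk <- complex(real = stats::rnorm(half), imaginary = stats::rnorm(half)) * mag
      if (n %% 2 == 0) xk[half] <- complex(real = stats::rnorm(1) * sqrt(2) * mag[half])
      spec_full <- c(0, xk,
                     if (n %% 2 == 0) Conj(rev(xk[-half])) else Conj(rev(xk)))
      x <- x + Re(stats::fft(spec_full, inverse = TRUE)) / n
    }
    x
  })
  attr(x, "fs") <- fs
  x
}

#' Welch power spectral density estimate
#'
#' Averaged periodogram over Hann-windowed, overlapping segments, one-sided
#' density scaling (total integrated power consistent with signal variance
#' for stationary zero-mean signals). The DC bin is dropped so the result is
#' a valid [psd_table()].
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param segment_length Samples per segment; at most `length(x)`. Default
#'   `min(length(x), 4 * fs)` (4-s segments).
#' @param overlap Fractional overlap between segments in `[0, 1)`.
#' @return A [psd_table()] on the grid `fs/segment_length, ..., fs/2`.
#' @export
welch_psd <- function(x, fs, segment_length = NULL, overlap = 0.5) {
  stopifnot(is.numeric(x))
  check_positive_scalar(fs, "fs")
  stopifnot(overlap >= 0, overlap < 1)
  if (is.null(segment_length)) segment_length <- min(length(x), round(4 * fs))
  segment_length <- as.integer(segment_length)
  if (segment_length < 8L) stop("`segment_length` must be at least 8", call. = FALSE)
  if (segment_length > length(x)) {
    stop("signal shorter than one segment", call. = FALSE)
  }
  step <- max(1L, round(segment_length * (1 - overlap)))
  starts <- seq(1L, length(x) - segment_length + 1L, by = step)
  w <- signal::hanning(segment_length)
  scale <- fs * sum(w^2)
  half <- floor(segment_length / 2)
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + segment_length - 1L)] * w
    X <- stats::fft(seg)
    p <- Mod(X[2:(half + 1L)])^2 / scale
    # one-sided: double everything except the Nyquist bin (even lengths)
    p <- p * 2
    if (segment_length %% 2 == 0) p[half] <- p[half] / 2
    acc <- acc + p
  }
  freqs <- (1:half) * fs / segment_length
  psd_table(freqs, acc / length(starts),
            meta = list(estimator = "welch", fs = fs,
                        segment_length = segment_length, overlap = overlap,
                        n_segments = length(starts)))
}
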