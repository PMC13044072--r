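# shared fixtures built in code

# flat PSD of constant density over [f_min, f_max]
flat_psd <- function(f_min = 1, f_max = 40, density = 1, by = 0.5) {
  f <- seq(f_min, f_max, by = by)
  psd_table(f, rep(density, length(f)))
}

# noiseless 1/f background plus one Gaussian peak
peak_psd <- function(center, amplitude = 2, sd = 1, beta = 1,
                     f_min = 1, f_max = 45, n_points = 89L) {
  spec <- synth_spec(background_amp = 1, background_exp = beta,
                     peaks = data.frame(center = center,
                                        amplitude = amplitude, sd = sd),
                     noise_sd = 0, f_min = f_min, f_max = f_max,
                     n_points = n_points)
  synth_psd(spec)
}

# PSD with two bit-identical bumps at 8 and 12 Hz: the grid and the bumps are
# symmetric in log-frequency about sqrt(8 * 12), so the detrend line absorbs
# the power-law exactly and both detrended peaks have equal prominence
twin_peak_psd <- function() {
  c0 <- log(sqrt(8 * 12))
  logf <- c0 + seq(-1, 1, length.out = 201)
  bump <- function(mu) 1.5 * exp(-(logf - log(mu))^2 / (2 * 0.08^2))
  v <- bump(8) + bump(12)
  f <- exp(logf)
  psd_table(f, f^-1 * exp(v))
}

# trapezoid integral, independent of the package's internals
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
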