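# applying schemes to spectra: classification, band power, comparisons,
# alignment, ratio conformity

test_that("classification follows the half-open interval convention", {
  s <- tbb_scheme()
  expect_identical(classify_frequency(9.0, s), "alpha1")
  expect_identical(classify_frequency(10.5, s), "alpha2")  # boundary -> upper band
  expect_identical(classify_frequency(25.0, s), "gamma1")
  expect_error(classify_frequency(0, s), "positive")
  # outside a closed scheme's coverage -> NA
  expect_true(is.na(classify_frequency(0.5, traditional_scheme())))
  expect_true(is.na(classify_frequency(150, traditional_scheme())))
})

test_that("classification agrees with a brute-force interval scan", {
  s <- tbb_scheme()
  b <- s$bands
  withr::with_seed(21, {
    f <- exp(stats::runif(1e4, log(0.05), log(500)))
    got <- classify_frequency(f, s)
    want <- vapply(f, function(x) b$label[x >= b$lower & x < b$upper][1],
                   character(1))
    expect_identical(got, want)
  })
})

test_that("band power of a flat PSD equals bandwidth within the support", {
  psd <- flat_psd(1, 40)
  bp <- band_power(psd, tbb_scheme())
  widths <- pmax(pmin(bp$upper, 40) - pmax(bp$lower, 1), 0)
  expect_equal(bp$absolute_power, widths, tolerance = 1e-9)
  expect_equal(sum(bp$relative_power), 1, tolerance = 1e-9)
})

test_that("band powers conserve the trapezoidal total and normalize", {
  spec <- synth_spec(peaks = data.frame(center = c(6, 10.5), amplitude = c(1, 2),
                                        sd = c(1, 1.2)),
                     noise_sd = 0.1, seed = 12)
  psd <- synth_psd(spec)
  bp <- band_power(psd, tbb_scheme())
  expect_equal(sum(bp$absolute_power), trapz(psd$freqs, psd$power),
               tolerance = 1e-9)
  expect_equal(sum(bp$relative_power), 1, tolerance = 1e-9)
})

test_that("a narrow 30 Hz peak concentrates power in gamma1", {
  psd <- peak_psd(30, amplitude = 10, sd = 0.8)
  bp <- band_power(psd, tbb_scheme())
  expect_identical(bp$label[which.max(bp$relative_power)], "gamma1")
  # dense numerical integration oracle for the gamma1 share
  f_dense <- seq(1, 45, length.out = 2e4)
  p_dense <- 1 / f_dense + 10 * exp(-(f_dense - 30)^2 / (2 * 0.8^2))
  lims <- bp[bp$label == "gamma1", c("lower", "upper")]
  in_g1 <- f_dense >= lims$lower & f_dense <= lims$upper
  oracle <- trapz(f_dense[in_g1], p_dense[in_g1]) / trapz(f_dense, p_dense)
  expect_equal(bp$relative_power[bp$label == "gamma1"], oracle, tolerance = 0.02)
})

test_that("band_power rejects empty overlap and honors the cap", {
  psd <- flat_psd(1, 40)
  expect_error(band_power(psd, traditional_scheme(), f_max_cap = 0.2),
               "overlap|positive")
  capped <- band_power(psd, tbb_scheme(), f_max_cap = 20)
  expect_lte(max(capped$upper), 20)
  expect_equal(sum(capped$absolute_power), 19, tolerance = 1e-9)
})

test_that("scheme comparison reflects bandwidth arithmetic on a flat PSD", {
  psd <- flat_psd(1, 40)
  cmp <- compare_schemes(psd, tbb_scheme(), traditional_scheme(),
                         names = c("tbb", "trad"))
  beta <- cmp[cmp$label == "beta", ]
  # geometric beta band 13.80-23.84 is narrower than traditional 13-30
  expect_lt(beta$relative_tbb, beta$relative_trad)
  # unmatched labels are reported one-sided
  expect_true(is.na(cmp$relative_tbb[cmp$label == "gamma"]))
  expect_true(is.na(cmp$relative_trad[cmp$label == "gamma2"]))
  same <- compare_schemes(psd, tbb_scheme(), tbb_scheme())
  expect_true(all(same$relative_diff == 0))
})

test_that("a 27 Hz peak is beta traditionally but gamma1 geometrically", {
  expect_identical(classify_frequency(27, traditional_scheme()), "beta")
  expect_identical(classify_frequency(27, tbb_scheme()), "gamma1")
  psd <- peak_psd(27, amplitude = 10, sd = 0.8)
  bp_trad <- band_power(psd, traditional_scheme())
  bp_tbb <- band_power(psd, tbb_scheme())
  expect_identical(bp_trad$label[which.max(bp_trad$relative_power)], "beta")
  expect_identical(bp_tbb$label[which.max(bp_tbb$relative_power)], "gamma1")
})

test_that("alignment reports nearest features and the theta/alpha headline", {
  rep_full <- schumann_alignment(tbb_scheme())
  # frozen full-precision deviations
  expect_equal(rep_full$headline$percent_deviation, 2.027797, tolerance = 1e-4)
  expect_identical(rep_full$headline$boundary_label, "theta/alpha1")
  row14 <- rep_full$table[rep_full$table$mode_freq == 14.1, ]
  expect_identical(row14$feature_label, "alpha2/beta")
  expect_equal(row14$percent_deviation, 2.123323, tolerance = 1e-4)
  # a mode equal to a scheme feature has zero deviation
  hit <- schumann_alignment(tbb_scheme(), modes = 10.5)
  expect_identical(hit$table$percent_deviation, 0)
  expect_error(schumann_alignment(tbb_scheme(), modes = numeric(0)), "empty")
})

test_that("alignment deviations are invariant under joint rescaling", {
  base <- schumann_alignment(tbb_scheme())$table$percent_deviation
  withr::with_seed(8, {
    for (s in stats::runif(3, 0.3, 4)) {
      scaled <- schumann_alignment(band_scheme(10.5 * s),
                                   modes = s * c(7.83, 14.1, 20.3, 26.0, 33.0))
      expect_equal(scaled$table$percent_deviation, base, tolerance = 1e-9)
    }
  })
})

test_that("classical comparator deviation is about 6% below the fundamental", {
  expect_equal(round(classical_deviation(10.5, 7.83)), 6)
  expect_equal(classical_deviation(10.5, 7.83), 6.130268, tolerance = 1e-5)
  expect_equal(classical_deviation(7.83 * 10 / 7, 7.83), 0, tolerance = 1e-12)
  expect_equal(classical_deviation(10.5, 7.35), 0, tolerance = 1e-12)
  expect_error(classical_deviation(-1), "positive")
})

test_that("the ratio fit recovers an exact geometric progression", {
  peaks <- 10.5 * 1.7275^(-2:2)
  fit <- estimate_geometric_ratio(peaks)
  expect_lt(abs(fit$R_hat - 1.7275), 1e-6)
  expect_lt(fit$residual_rms, 1e-9)
  expect_gt(fit$R_hat, 1)
  # the fitted anchor regenerates the peaks at integer indices
  n <- fit$index_assignment
  expect_equal(unname(fit$f_ref_hat * fit$R_hat^n), sort(peaks),
               tolerance = 1e-9)
})

test_that("an arithmetic progression fits worse than a geometric one", {
  rms_arith <- estimate_geometric_ratio(c(5, 10, 15, 20))$residual_rms
  rms_geo <- estimate_geometric_ratio(10.5 * 1.7275^(0:3))$residual_rms
  expect_gt(rms_arith, rms_geo)
  expect_gt(rms_arith, 1e-3)
})

test_that("degenerate peak sets are rejected", {
  expect_error(estimate_geometric_ratio(10), "at least 2")
  expect_error(estimate_geometric_ratio(c(8, 8, 8)), "at least 2")
  expect_error(estimate_geometric_ratio(c(-1, 5)), "positive")
})
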