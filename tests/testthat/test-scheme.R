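# scheme construction: exponential centers, geometric boundaries, inverse
# index mapping, alpha subdivision, classical comparator

test_that("center_frequency follows the exponential law", {
  expect_identical(center_frequency(10.5, 1.7275, 0), 10.5)
  expect_equal(round(center_frequency(10.5, 1.7275, -2), 2), 3.52)
  expect_equal(round(center_frequency(10.5, 1.7275, 1), 2), 18.14)
  # high-precision evaluation of 10.5 * 1.7275^3
  expect_equal(center_frequency(10.5, 1.7275, 3), 54.130678055, tolerance = 1e-9)
  # strictly increasing in n for R > 1
  expect_true(all(diff(center_frequency(10.5, 1.7275, -5:5)) > 0))
  expect_error(center_frequency(-1, 1.7275, 0), "positive")
  expect_error(center_frequency(10.5, 0, 0), "positive")
})

test_that("index_of inverts center_frequency", {
  expect_identical(index_of(10.5, 10.5, 1.7275), 0)
  expect_equal(index_of(center_frequency(10.5, 1.7275, 2), 10.5, 1.7275), 2)
  # ln(7.83 / 10.5) / ln(1.7275), frozen from independent evaluation
  expect_equal(index_of(7.83, 10.5, 1.7275), -0.5367222, tolerance = 1e-6)
  for (n in -5:5) {
    expect_lt(abs(index_of(center_frequency(10.5, 1.7275, n), 10.5, 1.7275) - n),
              1e-9)
  }
  expect_error(index_of(-3, 10.5, 1.7275), "positive")
  expect_error(index_of(5, 10.5, 0.9), "exceed 1")
})

test_that("geometric_boundary is the log-midpoint of its inputs", {
  # the familiar two-decimal separation frequencies follow from the
  # two-decimal center tabulation
  expect_equal(round(geometric_boundary(3.52, 6.07), 2), 4.62)
  expect_equal(round(geometric_boundary(6.07, 10.50), 2), 7.98)
  expect_identical(geometric_boundary(7.5, 7.5), 7.5)
  withr::with_seed(11, {
    a <- sort(stats::runif(200, 0.1, 100))
    b <- a * stats::runif(200, 1, 10)
    g <- geometric_boundary(a, b)
    expect_true(all(abs(log(g) - (log(a) + log(b)) / 2) < 1e-12))
    expect_true(all(g[a < b] > a[a < b] & g[a < b] < b[a < b]))
  })
  expect_error(geometric_boundary(0, 5), "positive")
  expect_error(geometric_boundary(6, 5), "exceed")
})

test_that("the default scheme tessellates with the expected boundaries", {
  s <- tbb_scheme()
  b <- s$bands
  expect_identical(b$label,
                   c("delta", "theta", "alpha1", "alpha2", "beta", "gamma1", "gamma2"))
  expect_identical(b$n, c(-2L, -1L, 0L, 0L, 1L, 2L, 3L))
  # frozen full-precision boundaries
  expect_equal(b$upper[1:6],
               c(4.6244747, 7.9887779, 10.5, 13.8006096, 23.8405638, 41.1845571),
               tolerance = 1e-6)
  expect_identical(b$lower[1], 0)
  expect_identical(b$upper[7], Inf)
  expect_identical(b$upper[-7], b$lower[-1])
  expect_identical(b$upper[3], 10.5)  # alpha split exactly at f_ref
})

test_that("the tabulated scheme reproduces the two-decimal reference ranges", {
  s <- tbb_scheme("tabulated")
  bounds <- s$bands$upper[1:6]
  expect_equal(round(bounds, 2), c(4.62, 7.98, 10.50, 13.80, 23.85, 41.22))
  # alpha/beta separation recomputes one unit below the commonly quoted 13.81
  expect_lt(abs(bounds[4] - 13.81), 0.02)
})

test_that("schemes are scale equivariant in f_ref", {
  base <- tbb_scheme()
  doubled <- band_scheme(21.0)
  expect_equal(doubled$bands$center, 2 * base$bands$center, tolerance = 1e-12)
  finite <- is.finite(base$bands$upper)
  expect_equal(doubled$bands$upper[finite], 2 * base$bands$upper[finite],
               tolerance = 1e-12)
  withr::with_seed(5, {
    for (s in stats::runif(5, 0.2, 8)) {
      scaled <- band_scheme(10.5 * s)
      expect_equal(scaled$bands$center, s * base$bands$center, tolerance = 1e-9)
      expect_equal(scaled$bands$upper[finite], s * base$bands$upper[finite],
                   tolerance = 1e-9)
    }
  })
})

test_that("a hand-computed three-band scheme matches", {
  s <- band_scheme(10.5, 2, -1, 1, subdivide_alpha = FALSE)
  expect_equal(s$bands$center, c(5.25, 10.5, 21))
  expect_equal(s$bands$lower, c(0, sqrt(5.25 * 10.5), sqrt(10.5 * 21)))
})

test_that("every positive frequency lands in exactly one band", {
  s <- tbb_scheme()
  grid <- exp(seq(log(0.01), log(1000), length.out = 1e4))
  labels <- classify_frequency(grid, s)
  expect_false(anyNA(labels))
  # brute-force membership scan agrees and is unique
  b <- s$bands
  hits <- vapply(grid, function(f) sum(f >= b$lower & f < b$upper), numeric(1))
  expect_true(all(hits == 1))
})

test_that("construction rejects bad parameters", {
  expect_error(band_scheme(R = 1), "exceed 1")
  expect_error(band_scheme(n_min = 3, n_max = 1), "smaller")
  expect_error(band_scheme(labels = c("a", "b")), "one name per index")
  expect_error(band_scheme(centers = c(1, 2, 3)), "one value per index")
  expect_error(band_scheme(centers = c(6, 5, 10, 18, 31, 54)), "increasing")
  # subdivision is a no-op when 0 is outside the index range
  s <- band_scheme(n_min = 1, n_max = 3, subdivide_alpha = TRUE)
  expect_identical(nrow(s$bands), 3L)
})

test_that("classical Titius-Bode centers use the 0.4 + 0.3 * 2^m multipliers", {
  tab <- classical_tb_centers(10.5)
  expect_equal(tab$center[tab$label == "alpha"], 10.5)
  expect_equal(tab$center[tab$label == "theta"], 7.35)
  expect_equal(tab$center[tab$label == "delta"], 4.20)
  expect_equal(tab$center[tab$label == "beta"], 16.80)
  expect_error(classical_tb_centers(0), "positive")
})

test_that("re-anchoring moves only the reference frequency", {
  s <- reanchor(tbb_scheme(), 9.8)
  expect_equal(s$f_ref, 9.8)
  expect_equal(s$bands$center, band_scheme(9.8)$bands$center)
  expect_error(reanchor(traditional_scheme(), 9.8), "geometric")
  a <- anchor_estimate(9.8, "iaf_peak", search_window = c(7, 14), quality = 1)
  expect_equal(reanchor(tbb_scheme(), a)$f_ref, 9.8)
})

test_that("scheme JSON validation catches hand-edited overlaps", {
  s <- tbb_scheme()
  s$bands$upper[2] <- s$bands$upper[2] + 0.5
  expect_error(validate_band_scheme(s), "tessellate")
})
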