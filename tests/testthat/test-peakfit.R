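test_that("a noiseless Gaussian on a flat background is recovered exactly", {
  q <- seq(0.08, 0.15, length.out = 600)
  truth <- list(center = 0.114, sigma = 0.002, amp = 1000, bg = 30)
  y <- truth$amp * exp(-(q - truth$center)^2 / (2 * truth$sigma^2)) + truth$bg
  cv <- intensity_curve(q, y)
  pk <- fit_bragg_series(cv, d_hint = 2 * pi / truth$center, max_order = 1,
                         sigma_hint = 0.002)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$center, truth$center, tolerance = 1e-6)
  expect_equal(pk$sigma, truth$sigma, tolerance = 1e-6)
  expect_equal(pk$amplitude, truth$amp, tolerance = 1e-6)
  # analytic identity area = amp * sigma * sqrt(2 pi)
  expect_equal(pk$area, pk$amplitude * pk$sigma * sqrt(2 * pi),
               tolerance = 1e-9)
})

test_that("a flat curve yields an empty peak list with a warning", {
  q <- seq(0.05, 1, length.out = 500)
  cv <- intensity_curve(q, rep(25, length(q)))
  expect_warning(pk <- fit_bragg_series(cv), "noise floor")
  expect_equal(nrow(pk), 0)
})

test_that("a seeded 10-order synthetic series is recovered near truth", {
  ff <- analytic_form_factors(bilayer_model(), 10)
  cv <- simulate_intensity_curve(ff, noise_scale = 1, seed = 42)
  pk <- fit_bragg_series(cv)
  expect_gte(nrow(pk), 8)
  for (i in seq_len(nrow(pk))) {
    n <- pk$order[i]
    expect_lt(abs(pk$center[i] - ff$q[n]), 0.5 * pk$sigma[i])
  }
})

test_that("lamellar spacing comes from the zero-intercept Bragg line", {
  pk <- data.frame(order = 1:5, center = 1:5 * (2 * pi / 55.07))
  expect_equal(lamellar_spacing(pk), 55.07)
  single <- data.frame(order = 1, center = 2 * pi / 69)
  expect_equal(lamellar_spacing(single), 69)
  # scale equivariance: q -> c q gives d -> d / c
  scaled <- pk; scaled$center <- scaled$center * 2
  expect_equal(lamellar_spacing(scaled), 55.07 / 2)
  # an outlier order breaks the series
  bad <- data.frame(order = c(1, 2, 3), center = c(0.1, 0.2, 0.5))
  expect_error(lamellar_spacing(bad), "inconsistent")
})

test_that("Lorentz correction follows |F_n| = sqrt(I_n q_n)", {
  pk <- data.frame(order = c(1, 2), area = c(100, 100))
  ff <- form_factor_magnitudes(pk, d_spacing = 55)
  expect_equal(ff$magnitude[2] / ff$magnitude[1], sqrt(2))
  # monotone in q at fixed area
  pk10 <- data.frame(order = 1:10, area = rep(7, 10))
  m <- form_factor_magnitudes(pk10, 55)$magnitude
  expect_true(all(diff(m) > 0))
  # zero and negative areas
  pk0 <- data.frame(order = 1:2, area = c(0, -5))
  expect_warning(ff0 <- form_factor_magnitudes(pk0, 55), "negative")
  expect_equal(ff0$magnitude, c(0, 0))
  # linear convention exposed
  ff1 <- form_factor_magnitudes(pk, 55, lorentz_exponent = 1)
  expect_equal(ff1$magnitude[2] / ff1$magnitude[1], 2)
})

test_that("noiseless simulator round trip recovers |F_n| within 1%", {
  ff <- analytic_form_factors(bilayer_model(), 10)
  counts_scale <- 5e4
  cv <- simulate_intensity_curve(ff, noise_scale = 0,
                                 counts_scale = counts_scale)
  pk <- fit_bragg_series(cv)
  rec <- form_factor_magnitudes(pk, lamellar_spacing(pk))
  expect_identical(rec$order, ff$order[rec$order])
  expect_equal(rec$magnitude / sqrt(counts_scale),
               ff$magnitude[rec$order], tolerance = 0.01)
})

test_that("the chain-correlation peak is fit on the in-plane axis", {
  q <- seq(0.9, 1.9, length.out = 800)
  y <- 900 * exp(-(q - 1.49)^2 / (2 * 0.06^2)) + 60 - 15 * q
  cv <- intensity_curve(q, y, axis = "in_plane_qpar")
  cp <- chain_peak(cv)
  expect_equal(cp$q_T, 1.49, tolerance = 1e-6)
  expect_equal(cp$sigma, 0.06, tolerance = 1e-4)
  # seeded gel-phase curve
  sim <- simulate_inplane_curve(q_T = 1.49, chain_area = 1216, seed = 3)
  cps <- chain_peak(sim)
  expect_lt(abs(cps$q_T - 1.49), 0.005)
  # no peak -> rejection
  flat <- intensity_curve(q, rep(40, length(q)), axis = "in_plane_qpar")
  expect_error(chain_peak(flat), "no resolvable")
  # wrong axis -> rejection
  expect_error(chain_peak(intensity_curve(q, y)), "in-plane")
})

test_that("curve files round-trip through delimited text", {
  cv <- simulate_inplane_curve(seed = 5, n_points = 50)
  path <- withr::local_tempfile(fileext = ".dat")
  write_intensity_curve(cv, path)
  back <- read_intensity_curve(path, axis = "in_plane_qpar")
  expect_equal(back$q, cv$q, tolerance = 1e-7)
  expect_equal(back$intensity, cv$intensity, tolerance = 1e-7)
  expect_equal(back$error, cv$error, tolerance = 1e-6)
})

test_that("malformed curves are rejected", {
  expect_error(intensity_curve(c(1, 1, 2), c(1, 2, 3)), "ascending")
  expect_error(intensity_curve(c(1, 2), c(-1, 2)), "non-negative")
  expect_error(intensity_curve(c(1, 2), c(1, 2, 3)), "equal length")
})
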