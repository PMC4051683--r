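make_abs_profile <- function(model, orders = 10, n = 1024) {
  p <- fourier_synthesis(analytic_form_factors(model, orders), n)
  truth <- eval_bilayer(model, p$z)
  A_L <- 40.95
  budget <- A_L * trapz(p$z, truth) / 2
  scale_to_absolute(p, budget, A_L, center_density = eval_bilayer(model, 0))
}

test_that("a profile minus itself is identically zero", {
  ab <- make_abs_profile(bilayer_model())
  d <- difference_profile(ab, ab)
  expect_true(all(abs(d$drho) < 1e-12))
})

test_that("an inserted Gaussian is recovered from the difference", {
  base <- bilayer_model()
  spiked <- bilayer_model(components = rbind(
    base$components, data.frame(center = 9, sigma = 2, amplitude = 0.03)))
  d <- difference_profile(make_abs_profile(spiked), make_abs_profile(base))
  truth <- 0.03 * (exp(-(d$z - 9)^2 / 8) + exp(-(d$z + 9)^2 / 8))
  expect_lt(max(abs(d$drho - truth)), 0.1 * max(truth))
  cm <- fit_components(d, k = 1, A_L = 40.95)
  expect_equal(cm$components$center, 9, tolerance = 0.05)
  expect_equal(cm$components$sigma, 2, tolerance = 0.1)
})

test_that("mismatched periods truncate to the smaller half-period", {
  a <- make_abs_profile(bilayer_model(d_spacing = 55.07))
  b <- make_abs_profile(bilayer_model(d_spacing = 52.41))
  expect_warning(d <- difference_profile(a, b), "truncating")
  expect_equal(max(d$z), 52.41 / 2)
  expect_error(difference_profile(
    fourier_synthesis(analytic_form_factors(bilayer_model(), 4)), a),
    "absolute")
})

test_that("a noiseless mirrored Gaussian is fit exactly", {
  truth <- data.frame(center = 10, sigma = 2, amplitude = 0.05)
  d <- make_difference(truth)
  cm <- fit_components(d, k = 1, A_L = 60)
  expect_equal(cm$components$center, 10, tolerance = 1e-6)
  expect_equal(cm$components$sigma, 2, tolerance = 1e-6)
  expect_equal(cm$components$amplitude, 0.05, tolerance = 1e-6)
  expect_lt(cm$residual_rms, 1e-9)
  expect_error(fit_components(d, k = 0, A_L = 60), "between 1 and 6")
})

test_that("4-component recovery holds over 25 seeded noisy profiles", {
  truth <- data.frame(center = c(22, 17.6, 9, 4.3),
                      sigma = c(5, 2, 2, 2),
                      amplitude = c(0.07, 0.06, 0.03, 0.03))
  A_L <- 40.95
  true_e <- A_L * truth$amplitude * truth$sigma * sqrt(2 * pi)
  errs_c <- c(); errs_e <- c()
  for (s in 1:25) {
    cm <- fit_components(make_difference(truth, noise = 0.02, seed = s),
                         k = 4, A_L = A_L)
    cc <- cm$components            # sorted by descending center
    tt <- truth[order(-truth$center), ]
    errs_c <- c(errs_c, abs(cc$center - tt$center))
    errs_e <- c(errs_e, abs(cc$electrons - true_e[order(-truth$center)]) /
                  true_e[order(-truth$center)])
  }
  expect_lt(median(errs_c), 0.5)
  expect_lt(median(errs_e), 0.05)
})

test_that("component electrons follow A_L * |amp| * sigma * sqrt(2 pi)", {
  expect_equal(component_electrons(0.013, 3.1, 60.6), 6.12,
               tolerance = 0.01 / 6.12)
  expect_equal(component_electrons(0, 3, 60), 0)
  expect_equal(component_electrons(0.02, 2, 120),
               2 * component_electrons(0.02, 2, 60))
  # the identity is not invariant under (amp*c, sigma/c) unless c = 1
  expect_equal(component_electrons(0.02 * 2, 2 / 2, 60),
               component_electrons(0.02, 2, 60))
})

test_that("population fractions reproduce the tabulated values", {
  fr <- population_fractions(c(17.2, 17.7, 16.0, 7.2))
  expect_equal(fr, c(29.5, 30.5, 27.5, 12.5), tolerance = 0.2 / 29.5)
  expect_equal(sum(fr), 100, tolerance = 1e-12)
  fr5 <- population_fractions(c(35.15, 35.15, 6.06))
  expect_equal(fr5, c(46, 46, 8), tolerance = 0.1 / 46)
  expect_equal(population_fractions(c(3, 3, 3)), rep(100 / 3, 3))
  expect_error(population_fractions(c(0, 0)), "positive")
})

test_that("embedded fraction splits populations at a depth boundary", {
  comp <- data.frame(center = c(22.0, 17.6, 9.0, 4.3),
                     electrons = c(17.2, 17.7, 16.0, 7.2))
  expect_equal(embedded_fraction(comp, 14), 39.9, tolerance = 0.1 / 39.9)
  expect_equal(embedded_fraction(comp, 2), 0)
  expect_equal(embedded_fraction(comp, 30), 100)
})

test_that("component tables round-trip through delimited text", {
  d <- make_difference(data.frame(center = 10, sigma = 2, amplitude = 0.05))
  cm <- fit_components(d, k = 1, A_L = 60)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_component_table(cm, path)
  tab <- read_component_table(path)
  expect_equal(tab$position, cm$components$center, tolerance = 1e-4)
  expect_equal(tab$electrons, cm$components$electrons, tolerance = 1e-4)
})
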