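test_that("a single negative order synthesizes a central trough", {
  ff <- form_factor_set(55, 1, 1, sign = -1L)
  p <- fourier_synthesis(ff, 256)
  expect_equal(p$rho[which.min(abs(p$z))], min(p$rho), tolerance = 1e-12)
  # pure cosine: maximum at the period edge
  expect_equal(max(p$rho), p$rho[1], tolerance = 1e-12)
})

test_that("synthesized profiles are even and periodic to machine precision", {
  ff <- analytic_form_factors(bilayer_model(), 8)
  p <- fourier_synthesis(ff, 512)
  expect_equal(p$rho, rev(p$rho), tolerance = 1e-12)
  expect_equal(p$rho[1], p$rho[length(p$rho)], tolerance = 1e-12)
})

test_that("all-zero magnitudes give the zero profile", {
  ff <- form_factor_set(55, 1:4, rep(0, 4), sign = rep(1L, 4))
  p <- fourier_synthesis(ff, 128)
  expect_true(all(p$rho == 0))
})

test_that("truncation error decreases monotonically with added orders", {
  m <- bilayer_model()
  model_err <- function(N) {
    p <- fourier_synthesis(analytic_form_factors(m, N), 1024)
    truth <- eval_bilayer(m, p$z)
    # relative profiles match up to an affine map; fix it by lsq
    A <- cbind(p$rho, 1)
    r <- truth - A %*% qr.solve(A, truth)
    sqrt(sum(r^2) / sum(truth^2))
  }
  errs <- vapply(1:10, model_err, numeric(1))
  expect_true(all(diff(errs) < 1e-12))
})

test_that("absolute scaling enforces the center and budget conditions", {
  m <- bilayer_model()
  ff <- analytic_form_factors(m, 10)
  p <- fourier_synthesis(ff, 1024)
  A_L <- 40.95
  truth <- eval_bilayer(m, p$z)
  budget <- A_L * trapz(p$z, truth) / 2
  c0 <- eval_bilayer(m, 0)
  ab <- scale_to_absolute(p, budget, A_L, center_density = c0)
  expect_equal(ab$rho[which.min(abs(ab$z))], c0, tolerance = 1e-9)
  expect_equal(A_L * trapz(ab$z, ab$rho), 2 * budget, tolerance = 1e-3)
  # round-trip L2 error bounds: truncation-dominated
  rel_l2 <- function(N) {
    pN <- fourier_synthesis(analytic_form_factors(m, N), 1024)
    aN <- scale_to_absolute(pN, budget, A_L, center_density = c0)
    sqrt(sum((aN$rho - truth)^2) / sum(truth^2))
  }
  expect_lt(rel_l2(10), 0.02)
  expect_lt(rel_l2(4), 0.10)
})

test_that("a deliberately de-scaled profile recovers its affine map", {
  m <- bilayer_model()
  p <- fourier_synthesis(analytic_form_factors(m, 10), 1024)
  A_L <- 40.95
  truth <- eval_bilayer(m, p$z)
  budget <- A_L * trapz(p$z, truth) / 2
  ab <- scale_to_absolute(p, budget, A_L, eval_bilayer(m, 0))
  # de-scale with a known affine map and recover it
  de <- density_profile(ab$z, (ab$rho - 0.07) / 3.2, ab$d_spacing,
                        scale_state = "relative")
  re <- scale_to_absolute(de, budget, A_L, eval_bilayer(m, 0))
  expect_equal(attr(re, "alpha"), 3.2, tolerance = 1e-6)
  expect_equal(attr(re, "beta"), 0.07, tolerance = 1e-6)
  expect_equal(re$rho, ab$rho, tolerance = 1e-6)
})

test_that("flipped sign conventions are corrected with a warning", {
  m <- bilayer_model()
  p <- fourier_synthesis(analytic_form_factors(m, 10), 1024)
  A_L <- 40.95
  truth <- eval_bilayer(m, p$z)
  budget <- A_L * trapz(p$z, truth) / 2
  flipped <- density_profile(p$z, -p$rho, p$d_spacing, "relative")
  expect_warning(ab <- scale_to_absolute(flipped, budget, A_L,
                                         eval_bilayer(m, 0)), "flipping")
  ref <- scale_to_absolute(p, budget, A_L, eval_bilayer(m, 0))
  expect_equal(ab$rho, ref$rho, tolerance = 1e-9)
})

test_that("degenerate flat profiles cannot be scaled", {
  flat <- density_profile(seq(-27.5, 27.5, length.out = 101), rep(0, 101),
                          55, "relative")
  expect_error(scale_to_absolute(flat, 400, 40), "degenerate")
})

test_that("landmarks locate the head-group peak and center density", {
  m <- bilayer_model()   # heads at +/-22
  p <- fourier_synthesis(analytic_form_factors(m, 10), 2048)
  A_L <- 40.95
  truth <- eval_bilayer(m, p$z)
  budget <- A_L * trapz(p$z, truth) / 2
  ab <- scale_to_absolute(p, budget, A_L, eval_bilayer(m, 0))
  lm <- landmark_report(ab)
  step <- diff(ab$z)[1]
  expect_lt(abs(lm$head_peak_z - 22), 5 * step)
  expect_equal(lm$center_value, eval_bilayer(m, 0), tolerance = 1e-6)
  expect_error(landmark_report(p), "absolute")
})

test_that("density profiles round-trip through delimited text", {
  m <- bilayer_model()
  p <- fourier_synthesis(analytic_form_factors(m, 6), 256)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_density_profile(p, path)
  back <- read_density_profile(path)
  expect_equal(back$z, p$z, tolerance = 1e-5)
  expect_equal(back$rho, p$rho, tolerance = 1e-6)
  expect_identical(back$scale_state, "relative")
  expect_equal(back$d_spacing, p$d_spacing)
})
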