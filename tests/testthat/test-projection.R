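test_that("PDB models load with element-derived atomic numbers", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(tiny_pdb_lines(), path)
  m <- load_atomic_model(path)
  expect_equal(nrow(m$atoms), 3)
  expect_identical(m$atoms$Z, c(7L, 6L, 8L))
})

test_that("only the first MODEL of a multi-model file is used", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(two_model_pdb_lines(), path)
  m <- load_atomic_model(path)
  expect_equal(nrow(m$atoms), 2)
  expect_true(all(m$atoms$x == 0))  # second model is shifted to x = 5
})

test_that("helix fixtures re-read with one atom per residue", {
  helix <- make_helix_model("GSNKGAIIGLM")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_model_pdb(helix, path)
  m <- load_atomic_model(path)
  expect_equal(nrow(m$atoms), 11)
  expect_equal(m$atoms$z, helix$atoms$z, tolerance = 1e-3)
})

test_that("a single atom projects to a Gaussian of area Z", {
  m <- atomic_model(data.frame(element = "C", Z = 6, x = 0, y = 0, z = 0))
  p <- project_density(m, fwhm = 4, grid = seq(-8, 8, by = 0.05))
  expect_equal(trapz(p$z, p$density), 6, tolerance = 1e-4)
  sigma <- 4 / (2 * sqrt(2 * log(2)))
  expect_equal(max(p$density), 6 / (sigma * sqrt(2 * pi)),
               tolerance = 1e-9)
})

test_that("two atoms at +/-5 A give an even profile of area 2Z", {
  m <- atomic_model(data.frame(element = "O", Z = 8, x = 0, y = 0,
                               z = c(-5, 5)))
  grid <- seq(-15, 15, by = 0.05)
  p <- project_density(m, grid = grid)
  expect_equal(p$density, rev(p$density), tolerance = 1e-12)
  expect_equal(trapz(p$z, p$density), 16, tolerance = 1e-3)
})

test_that("projection matches the brute-force oracle exactly", {
  helix <- make_helix_model("GSNKGAIIGLM")
  p <- project_density(helix)
  sg <- 4 / (2 * sqrt(2 * log(2)))
  brute <- vapply(p$z, function(zz)
    sum(helix$atoms$Z * dnorm(zz, helix$atoms$z, sg)), numeric(1))
  expect_lt(max(abs(p$density - brute)), 1e-9)
})

test_that("projection is linear in the model", {
  a1 <- make_helix_model("GSNK")$atoms
  a2 <- make_helix_model("AIIG")$atoms
  a2$z <- a2$z + 6
  grid <- seq(-15, 20, by = 0.1)
  p12 <- project_density(atomic_model(rbind(a1, a2)), grid = grid)
  p1 <- project_density(atomic_model(a1), grid = grid)
  p2 <- project_density(atomic_model(a2), grid = grid)
  expect_equal(p12$density, p1$density + p2$density, tolerance = 1e-12)
})

test_that("electrons are conserved under every pose", {
  helix <- make_kinked_model()
  total <- sum(helix$atoms$Z)
  for (ang in list(c(0, 0, 0), c(30, 60, 120), c(10, 170, 300))) {
    p <- project_density(helix, pose(4.2, ang))
    expect_equal(trapz(p$z, p$density), total, tolerance = 1e-4)
  }
})

test_that("periodic replication mirrors, folds and doubles the integral", {
  # narrow Gaussian at z0 < d/2: the period shows it and its mirror
  z0 <- 20; d <- 55
  grid <- seq(z0 - 4, z0 + 4, by = 0.02)
  prof <- data.frame(z = grid, density = dnorm(grid, z0, 0.4))
  rep <- replicate_periodic(prof, d)
  peaks <- rep$z[which(diff(sign(diff(rep$density))) == -2) + 1]
  expect_equal(sort(peaks), c(-z0, z0), tolerance = 0.2,
               ignore_attr = TRUE)
  # beyond the half period the image folds back: z0 > d/2 appears at
  # +/-(d - z0)
  z1 <- 30
  grid1 <- seq(z1 - 4, z1 + 4, by = 0.02)
  prof1 <- data.frame(z = grid1, density = dnorm(grid1, z1, 0.4))
  rep1 <- replicate_periodic(prof1, d)
  peaks1 <- rep1$z[which(diff(sign(diff(rep1$density))) == -2) + 1]
  expect_equal(sort(peaks1), c(-(d - z1), d - z1), tolerance = 0.2,
               ignore_attr = TRUE)
  expect_equal(trapz(rep$z, rep$density), 2 * trapz(prof$z, prof$density),
               tolerance = 1e-3)
  # an even input centered at 0 doubles at the center
  g2 <- seq(-5, 5, by = 0.02)
  even <- data.frame(z = g2, density = dnorm(g2, 0, 1))
  r2 <- replicate_periodic(even, d, out_z = g2)
  expect_equal(r2$density, 2 * dnorm(g2, 0, 1), tolerance = 1e-6)
})

test_that("a noiseless self-generated target yields the exact pose", {
  helix <- make_kinked_model()
  d <- 55.07
  tz <- seq(0, d / 2, length.out = 120)
  tp <- pose(8, c(0, 30, 45))
  target <- data.frame(
    z = tz,
    drho = replicate_periodic(project_density(helix, tp), d,
                              out_z = tz)$density)
  pf <- fit_pose(helix, target, d, z_grid = seq(6, 10, 0.5),
                 angle_grid = list(0, seq(0, 90, 15), seq(0, 90, 15)))
  expect_equal(pf$pose$z_shift, 8)
  expect_equal(pf$pose$angles, c(0, 30, 45))
  expect_lt(pf$score, 1e-12)
  # the true pose scores no worse than any other on its own target
  expect_false(pf$degenerate)
})

test_that("spherically degenerate models tie and are flagged", {
  m <- atomic_model(data.frame(element = "C", Z = 6, x = 0, y = 0, z = 0))
  d <- 50
  tz <- seq(0, 25, length.out = 80)
  target <- data.frame(
    z = tz,
    drho = replicate_periodic(project_density(m, pose(5, c(0, 0, 0))), d,
                              out_z = tz)$density)
  expect_warning(
    pf <- fit_pose(m, target, d, z_grid = c(5),
                   angle_grid = list(0, c(0, 45, 90), c(0, 45))),
    "degenerate")
  expect_true(pf$degenerate)
  expect_equal(pf$pose$angles[2], 0)  # lexicographic tie-break
  expect_error(fit_pose(m, target, d, z_grid = numeric(0)), "non-empty")
})
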