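# Forward simulator: ground-truth inputs for every pipeline stage.
#
# An analytic bilayer model (mirrored Gaussians on a water background)
# has closed-form Bragg form factors, so every downstream operation --
# peak fitting, Lorentz correction, sign assignment, Fourier synthesis,
# absolute scaling, decomposition -- can be validated by round trips
# against exact values.  All randomness flows through explicit seeds.

#' Analytic bilayer density model
#'
#' rho(z) = water_level + sum_j amp_j * G(z; c_j, s_j), where each
#' component with center c_j > 0 carries a mirrored partner at -c_j and
#' a component at c_j = 0 is a single central Gaussian.  The default
#' emulates a gel-phase phosphatidylcholine bilayer: electron-rich head
#' groups at +/-22 A and a methyl trough (negative amplitude) at the
#' bilayer center.
#'
#' @param d_spacing Lamellar period, Angstrom.
#' @param components Data.frame with columns `center` (>= 0), `sigma`,
#'   `amplitude` (e/A^3, relative to the water level).
#' @param water_level Background density, e/A^3 (default 0.333).
#' @return An object of class `bilayer_model`.
#' @export
bilayer_model <- function(d_spacing = 55.07,
                          components = data.frame(
                            center = c(22, 0),
                            sigma = c(3, 2.5),
                            amplitude = c(0.12, -0.14)),
                          water_level = 0.333) {
  stopifnot(d_spacing > 0,
            all(c("center", "sigma", "amplitude") %in% names(components)),
            all(components$center >= 0), all(components$sigma > 0))
  structure(list(d_spacing = d_spacing, components = components,
                 water_level = water_level),
            class = "bilayer_model")
}

#' Evaluate a bilayer model
#'
#' @param model A `bilayer_model`.
#' @param z Positions, Angstrom.
#' @return Density values, e/A^3.
#' @export
eval_bilayer <- function(model, z) {
  out <- rep(model$water_level, length(z))
  for (i in seq_len(nrow(model$components))) {
    cc <- model$components[i, ]
    out <- out + cc$amplitude * exp(-(z - cc$center)^2 / (2 * cc$sigma^2))
    if (cc$center > 0)
      out <- out + cc$amplitude * exp(-(z + cc$center)^2 / (2 * cc$sigma^2))
  }
  out
}

#' Exact Bragg form factors of a bilayer model
#'
#' F_n = sum_j m_j * amp_j * sigma_j * sqrt(2*pi)
#'         * exp(-q_n^2 sigma_j^2 / 2) * cos(q_n c_j),
#' with multiplicity m_j = 2 for mirrored pairs and 1 for a central
#' component; q_n = 2*pi*n/d.  This is the cosine transform of
#' rho - water_level, exact up to the (negligible) Gaussian tails
#' crossing the period boundary.
#'
#' @param model A `bilayer_model`.
#' @param max_order Highest order N >= 1.
#' @return A signed `form_factor_set`.
#' @export
analytic_form_factors <- function(model, max_order = 10) {
  stopifnot(max_order >= 1)
  qn <- 2 * pi * seq_len(max_order) / model$d_spacing
  Fn <- vapply(qn, function(q) {
    with(model$components,
         sum(ifelse(center > 0, 2, 1) * amplitude * sigma * sqrt(2 * pi) *
               exp(-q^2 * sigma^2 / 2) * cos(q * center)))
  }, numeric(1))
  form_factor_set(model$d_spacing, seq_len(max_order),
                  magnitude = abs(Fn), sign = ifelse(Fn >= 0, 1L, -1L))
}

#' Simulate a noisy reflectivity curve from form factors
#'
#' Inverts the Lorentz step (peak area I_n = |F_n|^(1/e)/q_n, matching
#' the `lorentz_exponent` convention of [form_factor_magnitudes()]),
#' places a Gaussian line at each Bragg position, adds a linear
#' background, and applies Poisson counting noise.  `noise_scale = 1`
#' gives plain Poisson statistics at the simulated count rate;
#' `noise_scale = 0` is noiseless; other values scale the relative
#' fluctuation by resampling at an adjusted gain.  Identical seeds give
#' identical curves.
#'
#' @param ffset A `form_factor_set`.
#' @param noise_scale Relative-noise multiplier (0 = noiseless).
#' @param background `c(intercept, slope)` counts (default c(50, -10)).
#' @param seed Integer RNG seed (required when noise_scale > 0).
#' @param q_range Two-element q window (default covers all orders).
#' @param n_points Curve length (default 4000).
#' @param peak_sigma Gaussian line width, Angstrom^-1 (default 0.003).
#' @param counts_scale Multiplier setting the overall count rate
#'   (default 5e4).
#' @param lorentz_exponent Convention shared with the analysis step.
#' @return An `intensity_curve` with a counting-error column.
#' @export
simulate_intensity_curve <- function(ffset, noise_scale = 1,
                                     background = c(50, -10), seed = NULL,
                                     q_range = NULL, n_points = 4000,
                                     peak_sigma = 0.003,
                                     counts_scale = 5e4,
                                     lorentz_exponent = 0.5) {
  stopifnot(inherits(ffset, "form_factor_set"))
  if (noise_scale > 0 && is.null(seed))
    stop("a seed is required when simulating counting noise")
  if (is.null(q_range))
    q_range <- c(max(min(ffset$q) - 0.05, 1e-3), max(ffset$q) + 0.05)
  q <- seq(q_range[1], q_range[2], length.out = n_points)
  areas <- counts_scale * ffset$magnitude^(1 / lorentz_exponent) / ffset$q
  lam <- background[1] + background[2] * q
  lam <- pmax(lam, 0)
  for (i in seq_along(areas)) {
    lam <- lam + areas[i] / (peak_sigma * sqrt(2 * pi)) *
      exp(-(q - ffset$q[i])^2 / (2 * peak_sigma^2))
  }
  if (noise_scale > 0) {
    g <- noise_scale^2
    y <- withr::with_seed(seed, stats::rpois(length(lam), lam / g) * g)
    err <- noise_scale * sqrt(lam)
  } else {
    y <- lam
    err <- sqrt(lam)
  }
  intensity_curve(q, y, error = err, axis = "out_of_plane_qz")
}

#' Simulate an in-plane curve with chain and plaque peaks
#'
#' Gaussian chain-correlation peak plus optional monoclinic [110]/[200]
#' plaque reflections on a linear background, with Poisson noise as in
#' [simulate_intensity_curve()].
#'
#' @param q_T Chain peak position (default 1.49 A^-1).
#' @param chain_area Chain peak area (counts * A^-1).
#' @param chain_sigma Chain peak width.
#' @param plaque Optional list(lattice, areas = c(a110, a200),
#'   sigma).
#' @param background `c(intercept, slope)`.
#' @param noise_scale,seed As in [simulate_intensity_curve()].
#' @param q_range,n_points Curve sampling.
#' @return An `intensity_curve` on the in-plane axis.
#' @export
simulate_inplane_curve <- function(q_T = 1.49, chain_area = 1216,
                                   chain_sigma = 0.065, plaque = NULL,
                                   background = c(80, -20),
                                   noise_scale = 1, seed = NULL,
                                   q_range = c(0.9, 1.9),
                                   n_points = 2000) {
  if (noise_scale > 0 && is.null(seed))
    stop("a seed is required when simulating counting noise")
  q <- seq(q_range[1], q_range[2], length.out = n_points)
  lam <- pmax(background[1] + background[2] * q, 0)
  lam <- lam + chain_area / (chain_sigma * sqrt(2 * pi)) *
    exp(-(q - q_T)^2 / (2 * chain_sigma^2))
  if (!is.null(plaque)) {
    qs <- c(reciprocal_q(plaque$lattice, 1, 1),
            reciprocal_q(plaque$lattice, 2, 0))
    sg <- if (is.null(plaque$sigma)) 0.02 else plaque$sigma
    for (i in 1:2)
      lam <- lam + plaque$areas[i] / (sg * sqrt(2 * pi)) *
        exp(-(q - qs[i])^2 / (2 * sg^2))
  }
  if (noise_scale > 0) {
    g <- noise_scale^2
    y <- withr::with_seed(seed, stats::rpois(length(lam), lam / g) * g)
    err <- noise_scale * sqrt(lam)
  } else {
    y <- lam
    err <- sqrt(lam)
  }
  intensity_curve(q, y, error = err, axis = "in_plane_qpar")
}

#' Idealized helical pseudo-atom model of a peptide
#'
#' One pseudo-atom per residue on an ideal alpha-helix (rise 1.5 A,
#' twist 100 degrees, radius 2.3 A by default), centered at the origin.
#' Each pseudo-atom carries the residue's electron count, with one water
#' (10 e-) removed per peptide bond from the second residue on, so the
#' total equals the condensation-formula electron count of the peptide.
#'
#' @param sequence One-letter amino-acid sequence.
#' @param rise Rise per residue, Angstrom.
#' @param twist Twist per residue, degrees.
#' @param radius Helix radius, Angstrom.
#' @return An `atomic_model` of pseudo-atoms (element `"X"` entries are
#'   stored as `"C"` placeholders with explicit Z).
#' @export
make_helix_model <- function(sequence, rise = 1.5, twist = 100,
                             radius = 2.3) {
  f_e <- vapply(strsplit(sequence, "")[[1]], function(a)
    electrons_of_formula(residue_formula(a)), numeric(1))
  n <- length(f_e)
  Zres <- f_e - c(0, rep(10, n - 1))  # condensation water per bond
  i <- seq_len(n) - 1
  th <- i * twist * pi / 180
  z <- i * rise
  z <- z - mean(z)
  atomic_model(data.frame(element = "C", Z = as.integer(Zres),
                          x = radius * cos(th), y = radius * sin(th),
                          z = z, stringsAsFactors = FALSE),
               source_id = paste0("helix:", sequence))
}

#' Write an atomic model as a minimal PDB file
#'
#' One ATOM record per atom (CA names, residue ALA); pseudo-atom models
#' keep their coordinates but the element column is written as carbon,
#' so a re-read model reproduces atom count and geometry, not
#' pseudo-electron numbers.
#'
#' @param model An `atomic_model`.
#' @param path Output path.
#' @export
write_model_pdb <- function(model, path) {
  at <- model$atoms
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %2s",
    seq_len(nrow(at)), seq_len(nrow(at)), at$x, at$y, at$z,
    ifelse(at$element == "X", "C", at$element))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a reproducible fixture pack
#'
#' Emits, under `dir`: gel- and fluid-state reflectivity curves
#' (d = 55.07 and 68.97 A), a two-hydration swelling pair for sign
#' assignment, an in-plane curve with the chain peak at 1.49 A^-1 plus
#' monoclinic plaque reflections (a = 9.76, b = 7.56, gamma = 103), and
#' a helical peptide PDB fixture, together with a JSON manifest listing
#' every file with its generating parameters.  Identical seeds
#' regenerate byte-identical packs.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer RNG seed.
#' @param noise_scale Counting-noise level for the curves (default 1).
#' @return Invisibly, the manifest as a list.
#' @export
write_fixtures <- function(dir, seed, noise_scale = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gel <- bilayer_model(d_spacing = 55.07)
  fluid <- bilayer_model(
    d_spacing = 68.97,
    components = data.frame(center = c(22, 0), sigma = c(3.5, 3),
                            amplitude = c(0.08, -0.09)))
  swollen <- bilayer_model(d_spacing = 60)   # same bilayer, more water
  manifest <- list(seed = seed, noise_scale = noise_scale, files = list())
  emit <- function(name, curve, params) {
    write_intensity_curve(curve, file.path(dir, name))
    manifest$files[[name]] <<- params
  }
  emit("gel_reflectivity.dat",
       simulate_intensity_curve(analytic_form_factors(gel, 10),
                                noise_scale, seed = seed),
       list(kind = "reflectivity", d_spacing = 55.07, orders = 10))
  emit("fluid_reflectivity.dat",
       simulate_intensity_curve(analytic_form_factors(fluid, 4),
                                noise_scale, seed = seed + 1),
       list(kind = "reflectivity", d_spacing = 68.97, orders = 4))
  emit("swelling_a.dat",
       simulate_intensity_curve(analytic_form_factors(gel, 8),
                                noise_scale, seed = seed + 2),
       list(kind = "swelling", d_spacing = 55.07, orders = 8))
  emit("swelling_b.dat",
       simulate_intensity_curve(analytic_form_factors(swollen, 8),
                                noise_scale, seed = seed + 3),
       list(kind = "swelling", d_spacing = 60, orders = 8))
  lat <- lattice2d(9.76, 7.56, 103)
  emit("inplane_plaques.dat",
       simulate_inplane_curve(q_T = 1.49, plaque = list(
         lattice = lat, areas = c(73, 98), sigma = 0.02),
         noise_scale = noise_scale, seed = seed + 4),
       list(kind = "inplane", q_T = 1.49, lattice = unclass(lat)))
  helix <- make_helix_model("GSNKGAIIGLM")
  write_model_pdb(helix, file.path(dir, "helix_25_35.pdb"))
  manifest$files[["helix_25_35.pdb"]] <-
    list(kind = "pdb", sequence = "GSNKGAIIGLM",
         electrons = sum(helix$atoms$Z))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
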