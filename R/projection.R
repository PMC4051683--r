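# Projection of atomic structures into 1-D electron densities and
# rigid-body pose fitting against experimental difference profiles.
#
# Each atom is broadened by a Gaussian of fixed FWHM (default 4 A,
# emulating thermal motion) weighted by its electron number, and the
# broadened densities are summed along the bilayer normal.  Because the
# lamellar stack is centrosymmetric and periodic, the mirrored leaflet
# partner and images from neighboring bilayers are added before
# comparing with a measured difference density.  The pose (z-shift plus
# z-y-z Euler rotation) is found by exhaustive grid search.

#' Load an atomic model from a PDB file
#'
#' Reads ATOM/HETATM records via `bio3d::read.pdb`; only the first MODEL
#' of a multi-model (NMR) file is used.  Atomic numbers are derived from
#' the element column, falling back to the leading letter of the atom
#' name.  Hydrogens are kept when present.
#'
#' @param path PDB file path.
#' @return An object of class `atomic_model`: data.frame `atoms` with
#'   columns `element`, `Z`, `x`, `y`, `z`; field `source_id`.
#' @export
load_atomic_model <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  elesy <- at$elesy
  blank <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[blank] <- substr(trimws(at$elety[blank]), 1, 1)
  el <- trimws(elesy)
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
  known <- el %in% .elements$symbol
  if (any(!known)) {
    # two-letter guesses that fail may be one-letter elements (e.g. "CA")
    el1 <- substr(el, 1, 1)
    fix <- !known & el1 %in% .elements$symbol
    el[fix] <- el1[fix]
    known <- el %in% .elements$symbol
  }
  if (any(!known))
    stop("unknown element in atom record(s): ",
         paste(unique(at$elety[!known]), collapse = ", "))
  atomic_model(data.frame(element = el, Z = atomic_number(el),
                          x = at$x, y = at$y, z = at$z,
                          stringsAsFactors = FALSE),
               source_id = basename(path))
}

#' Construct an atomic model
#'
#' @param atoms Data.frame with columns `element`, `Z`, `x`, `y`, `z`.
#' @param source_id Provenance label (e.g. a PDB entry name).
#' @return An `atomic_model`.
#' @export
atomic_model <- function(atoms, source_id = "model") {
  stopifnot(nrow(atoms) >= 1,
            all(c("element", "Z", "x", "y", "z") %in% names(atoms)),
            all(atoms$Z >= 1))
  structure(list(atoms = atoms, source_id = source_id),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat("<atomic_model> ", x$source_id, ": ", nrow(x$atoms), " atoms, ",
      sum(x$atoms$Z), " electrons\n", sep = "")
  invisible(x)
}

#' Rigid-body pose
#'
#' @param z_shift Translation along the bilayer normal, Angstrom.
#' @param angles Three z-y-z Euler angles in degrees, wrapped to
#'   \[0, 360).
#' @return A `pose` object.
#' @export
pose <- function(z_shift = 0, angles = c(0, 0, 0)) {
  stopifnot(length(angles) == 3)
  structure(list(z_shift = z_shift, angles = angles %% 360),
            class = "pose")
}

# z-y-z Euler rotation matrix, degrees.
.euler_zyz <- function(angles) {
  r <- angles * pi / 180
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3, 3)
  Rz(r[1]) %*% Ry(r[2]) %*% Rz(r[3])
}

#' Apply a pose to an atomic model
#'
#' Rotates about the model centroid, then shifts along z.
#'
#' @param model An `atomic_model`.
#' @param p A `pose`.
#' @return A transformed `atomic_model`.
#' @export
apply_pose <- function(model, p) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  xyz <- sweep(xyz, 2, ctr)
  xyz <- xyz %*% t(.euler_zyz(p$angles))
  xyz <- sweep(xyz, 2, ctr, FUN = "+")
  out <- model$atoms
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3] + p$z_shift
  atomic_model(out, model$source_id)
}

#' Project an atomic model into a 1-D electron density
#'
#' profile(z) = sum_a Z_a * Normal(z; z_a, sigma), with
#' sigma = fwhm / (2*sqrt(2*log(2))).  The default grid extends 4 sigma
#' beyond the extreme atoms so the integral equals the total electron
#' count to better than 0.01%.
#'
#' @param model An `atomic_model`.
#' @param p Optional `pose` applied first.
#' @param grid Optional z grid; default: extreme atoms +/- 4 sigma at
#'   ~0.1 A step.
#' @param fwhm Gaussian broadening FWHM, Angstrom (default 4).
#' @param heavy_only Drop hydrogens before projecting (default FALSE).
#' @return Data.frame with columns `z`, `density` (e/Angstrom).
#' @export
project_density <- function(model, p = NULL, grid = NULL, fwhm = 4,
                            heavy_only = FALSE) {
  stopifnot(inherits(model, "atomic_model"), fwhm > 0)
  if (!is.null(p)) model <- apply_pose(model, p)
  at <- model$atoms
  if (heavy_only) at <- at[at$element != "H", , drop = FALSE]
  if (!nrow(at)) stop("no atoms to project")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  if (is.null(grid)) {
    grid <- seq(min(at$z) - 4 * sigma, max(at$z) + 4 * sigma,
                by = min(0.1, sigma / 8))
  }
  dens <- colSums(at$Z * exp(-outer(at$z, grid, "-")^2 / (2 * sigma^2))) /
    (sigma * sqrt(2 * pi))
  data.frame(z = grid, density = dens)
}

#' Replicate a projected profile across leaflets and neighbor bilayers
#'
#' The measured lamellar density is centrosymmetric and d-periodic, so a
#' single molecule's projection p(z) appears together with its mirrored
#' leaflet partner p(-z) and the images of both shifted by multiples of
#' the lamellar period: total(z) = sum_m p(z + m d) + p(-z + m d),
#' folded into one period \[-d/2, d/2\].  The integral over one period is
#' twice the input integral (molecule + mirror partner).
#'
#' @param profile Data.frame `z`, `density` (z-registered absolutely).
#' @param d_spacing Lamellar period, Angstrom.
#' @param out_z Optional output grid over \[-d/2, d/2\].
#' @return Data.frame with columns `z`, `density`.
#' @export
replicate_periodic <- function(profile, d_spacing, out_z = NULL) {
  stopifnot(d_spacing > 0)
  if (is.null(out_z))
    out_z <- seq(-d_spacing / 2, d_spacing / 2,
                 length.out = max(257, length(profile$z)))
  zr <- range(profile$z)
  M <- ceiling((max(abs(zr)) + d_spacing / 2) / d_spacing)
  dens <- numeric(length(out_z))
  for (m in -M:M) {
    dens <- dens + stats::approx(profile$z, profile$density,
                                 xout = out_z + m * d_spacing,
                                 yleft = 0, yright = 0)$y
    dens <- dens + stats::approx(profile$z, profile$density,
                                 xout = -out_z + m * d_spacing,
                                 yleft = 0, yright = 0)$y
  }
  data.frame(z = out_z, density = dens)
}

#' Fit a rigid-body pose against a measured difference profile
#'
#' Exhaustive grid search over z-shift and z-y-z Euler angles.  Each
#' candidate is projected, replicated across leaflets and neighbor
#' bilayers, restricted to the measurement domain \[0, d/2\], and
#' compared to the target by least squares, optionally with a single
#' non-negative free amplitude scale (absorbing the unknown
#' molecule-per-lipid stoichiometry).  The first Euler angle rotates
#' about the projection axis and never changes the score; ties are
#' broken by smaller |z_shift|, then lexicographically smaller angles.
#'
#' @param model An `atomic_model`.
#' @param target Data.frame `z`, `drho` (or `density`) on \[0, d/2\].
#' @param d_spacing Lamellar period, Angstrom.
#' @param z_grid Candidate z-shifts (default `seq(0, d/4, 0.5)`).
#' @param angle_grid Candidate angles in degrees, either a single vector
#'   used for all three Euler angles or a list of three vectors
#'   (default 15 degree steps; beta restricted to \[0, 180\]).
#' @param scale_free Allow a free non-negative amplitude scale
#'   (default TRUE).
#' @param fwhm Broadening FWHM passed to [project_density()].
#' @return List of class `pose_fit`: `pose`, `scale`, `score`,
#'   `degenerate` (TRUE when distinct rotations tie).
#' @export
fit_pose <- function(model, target, d_spacing, z_grid = NULL,
                     angle_grid = NULL, scale_free = TRUE, fwhm = 4) {
  stopifnot(inherits(model, "atomic_model"), d_spacing > 0)
  ycol <- if ("drho" %in% names(target)) "drho" else "density"
  tz <- target$z; ty <- target[[ycol]]
  if (is.null(z_grid)) z_grid <- seq(0, d_spacing / 4, by = 0.5)
  if (is.null(angle_grid))
    angle_grid <- list(seq(0, 345, 15), seq(0, 180, 15), seq(0, 345, 15))
  if (!is.list(angle_grid))
    angle_grid <- list(angle_grid, angle_grid[angle_grid <= 180], angle_grid)
  if (!length(z_grid) || !all(lengths(angle_grid) > 0))
    stop("pose grids must be non-empty")
  alpha0 <- sort(angle_grid[[1]])[1]  # never affects the z-projection
  best <- NULL; n_best_rot <- 0L
  for (beta in angle_grid[[2]]) for (gamma in angle_grid[[3]]) {
    prof <- project_density(model, pose(0, c(alpha0, beta, gamma)),
                            fwhm = fwhm)
    for (zs in z_grid) {
      shifted <- data.frame(z = prof$z + zs, density = prof$density)
      calc <- replicate_periodic(shifted, d_spacing, out_z = tz)$density
      if (scale_free) {
        cc <- sum(calc^2)
        s <- if (cc > 0) max(0, sum(calc * ty) / cc) else 0
      } else s <- 1
      sc <- sum((ty - s * calc)^2)
      cand <- list(pose = pose(zs, c(alpha0, beta, gamma)),
                   scale = s, score = sc)
      if (is.null(best)) { best <- cand; n_best_rot <- 1L; next }
      tol <- 1e-9 * (1 + best$score)
      if (sc < best$score - tol) {
        best <- cand; n_best_rot <- 1L
      } else if (abs(sc - best$score) <= tol) {
        n_best_rot <- n_best_rot + 1L
        better_tie <-
          abs(zs) < abs(best$pose$z_shift) - 1e-12 ||
          (abs(zs) <= abs(best$pose$z_shift) + 1e-12 &&
           (beta < best$pose$angles[2] ||
            (beta == best$pose$angles[2] && gamma < best$pose$angles[3])))
        if (better_tie) best <- cand
      }
    }
  }
  degenerate <- n_best_rot > 1L
  if (degenerate)
    warning("pose fit is degenerate: multiple grid poses score equally")
  structure(c(best, list(degenerate = degenerate)), class = "pose_fit")
}

#' @export
print.pose_fit <- function(x, ...) {
  cat("<pose_fit> z_shift =", x$pose$z_shift, "A, angles =",
      paste(x$pose$angles, collapse = "/"), "deg, scale =",
      signif(x$scale, 4), ", score =", signif(x$score, 6), "\n")
  invisible(x)
}
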