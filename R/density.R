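# Fourier synthesis of 1-D electron-density profiles and absolute scaling.
#
# With signed form factors the bilayer profile over one lamellar period is
# the cosine series rho*(z) = (2/d) sum_n nu_n |F_n| cos(2 pi n z / d),
# known only up to an affine transform.  The absolute e/A^3 scale is
# fixed by two physical conditions: a known electron density at the
# bilayer center (0.22 e/A^3 for terminal CH2/CH3 groups in a pure lipid
# gel bilayer; up to 0.33 e/A^3, the average amino-acid density, when a
# peptide occupies the center) and electron conservation -- the profile
# integrated over the period and multiplied by the area per lipid must
# equal the electron content of two leaflets.

#' Fourier synthesis of a relative density profile
#'
#' @param ffset A `form_factor_set` with signs assigned.
#' @param grid_points Number of grid points over one period
#'   (default 1024; must be at least 4 per observed order).
#' @return An object of class `density_profile` with fields `z`
#'   (symmetric grid over \[-d/2, d/2\]), `rho`, `d_spacing`,
#'   `scale_state = "relative"`, `rho_water`.
#' @export
fourier_synthesis <- function(ffset, grid_points = 1024) {
  stopifnot(inherits(ffset, "form_factor_set"))
  if (anyNA(ffset$sign)) stop("signs must be assigned before synthesis")
  N <- length(ffset$order)
  if (grid_points < 4 * N)
    stop("grid_points must be at least 4 per observed order")
  d <- ffset$d_spacing
  z <- seq(-d / 2, d / 2, length.out = grid_points + 1)
  rho <- (2 / d) * colSums(
    (ffset$sign * ffset$magnitude) *
      cos(outer(2 * pi * ffset$order / d, z)))
  density_profile(z, rho, d, scale_state = "relative")
}

#' Construct a density profile
#'
#' @param z Symmetric grid over one period \[-d/2, d/2\], Angstrom.
#' @param rho Density values (relative units or e/A^3).
#' @param d_spacing Lamellar period, Angstrom.
#' @param scale_state `"relative"` or `"absolute"`.
#' @param rho_water Reference bulk-water density, e/A^3.
#' @return A `density_profile`.
#' @export
density_profile <- function(z, rho, d_spacing,
                            scale_state = c("relative", "absolute"),
                            rho_water = 0.333) {
  scale_state <- match.arg(scale_state)
  stopifnot(length(z) == length(rho), d_spacing > 0)
  if (max(abs(rev(z) + z)) > 1e-9 * d_spacing)
    stop("z grid must be symmetric about 0")
  structure(list(z = as.numeric(z), rho = as.numeric(rho),
                 d_spacing = d_spacing, scale_state = scale_state,
                 rho_water = rho_water),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat("<density_profile> d =", sprintf("%.3f", x$d_spacing), "A,",
      length(x$z), "points,", x$scale_state, "scale\n")
  invisible(x)
}

# Trapezoidal integral on the profile grid.
.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# rho at z = 0 by linear interpolation (exact when the grid contains 0).
.rho_at <- function(profile, z0) {
  stats::approx(profile$z, profile$rho, xout = z0, rule = 2)$y
}

#' Scale a relative profile to absolute electron density
#'
#' Solves the affine map rho -> alpha*rho + beta such that (i) the
#' density at the bilayer center equals `center_density` and (ii) the
#' profile integrated over the period times the area per lipid equals
#' the electron content of two leaflets, A_L * int rho dz = 2 * budget.
#' A positive alpha is enforced; a negative solution means the sign
#' convention of the input was flipped, and the profile is negated with
#' a warning.
#'
#' @param profile A relative `density_profile`.
#' @param budget Electrons per lipid in one leaflet
#'   (see [leaflet_electron_budget()]).
#' @param A_L Area per lipid, Angstrom^2.
#' @param center_density Target density at z = 0, e/A^3 (0.22 for a
#'   lipid-only gel bilayer; scan up to 0.33 for peptide-filled centers).
#' @return An absolute `density_profile`; the applied `alpha`, `beta`
#'   are attached as attributes.
#' @export
scale_to_absolute <- function(profile, budget, A_L, center_density = 0.22) {
  stopifnot(inherits(profile, "density_profile"))
  if (profile$scale_state != "relative")
    stop("profile is already on an absolute scale")
  stopifnot(budget > 0, A_L > 0)
  d <- profile$d_spacing
  I1 <- .trapz(profile$z, profile$rho)   # integral of rho*
  r0 <- .rho_at(profile, 0)
  # alpha*r0 + beta = c0 ; alpha*A_L*I1 + beta*A_L*d = 2*budget
  det <- r0 * A_L * d - I1 * A_L
  if (abs(det) < 1e-12 * (1 + abs(r0) * A_L * d))
    stop("degenerate profile: affine scale is not determined")
  a <- matrix(c(r0, A_L * I1, 1, A_L * d), nrow = 2)
  sol <- solve(a, c(center_density, 2 * budget))
  alpha <- sol[1]; beta <- sol[2]
  rho <- profile$rho
  if (alpha < 0) {
    warning("negative scale factor: flipping the profile sign convention")
    rho <- -rho
    a <- matrix(c(-r0, -A_L * I1, 1, A_L * d), nrow = 2)
    sol <- solve(a, c(center_density, 2 * budget))
    alpha <- sol[1]; beta <- sol[2]
  }
  out <- density_profile(profile$z, alpha * rho + beta, d,
                         scale_state = "absolute",
                         rho_water = profile$rho_water)
  attr(out, "alpha") <- alpha
  attr(out, "beta") <- beta
  attr(out, "budget") <- budget
  attr(out, "A_L") <- A_L
  attr(out, "center_density") <- center_density
  out
}

#' Landmark report for an absolute profile
#'
#' Locates the head-group peak (the density maximum in the outer quarter
#' of the half-bilayer, z in (d/4, d/2)) and reports the center density.
#'
#' @param profile An absolute `density_profile`.
#' @return List with `head_peak_z` (Angstrom), `center_value` and
#'   `head_value` (e/A^3).
#' @export
landmark_report <- function(profile) {
  stopifnot(inherits(profile, "density_profile"))
  if (profile$scale_state != "absolute")
    stop("landmark_report expects an absolute profile")
  d <- profile$d_spacing
  sel <- profile$z > d / 4 & profile$z < d / 2
  zs <- profile$z[sel]; rs <- profile$rho[sel]
  if (max(rs) - min(rs) < 1e-12 * (1 + abs(max(rs)))) {
    warning("flat profile in the head-group region; landmark is degenerate")
    return(list(head_peak_z = NA_real_,
                center_value = .rho_at(profile, 0),
                head_value = NA_real_))
  }
  i <- which.max(rs)
  list(head_peak_z = zs[i], center_value = .rho_at(profile, 0),
       head_value = rs[i])
}

#' Read a density profile written by [write_density_profile()]
#'
#' @param path File path.
#' @return A `density_profile`.
#' @export
read_density_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NULL) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(default)
    as.numeric(sub(paste0("^# ", key, ": *"), "", m[1]))
  }
  state <- sub("^# scale_state: *", "",
               grep("^# scale_state:", hdr, value = TRUE)[1])
  tab <- utils::read.table(path, comment.char = "#")
  density_profile(tab[[1]], tab[[2]], d_spacing = get("d_spacing"),
                  scale_state = state,
                  rho_water = get("rho_water", 0.333))
}

#' Write a density profile as delimited text
#'
#' @param profile A `density_profile`.
#' @param path Output path.
#' @export
write_density_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# d_spacing: ", format(profile$d_spacing)),
    paste0("# scale_state: ", profile$scale_state),
    paste0("# rho_water: ", format(profile$rho_water)),
    if (!is.null(attr(profile, "A_L")))
      paste0("# A_L: ", format(attr(profile, "A_L"))),
    if (!is.null(attr(profile, "budget")))
      paste0("# budget: ", format(attr(profile, "budget"))),
    if (!is.null(attr(profile, "center_density")))
      paste0("# center_density: ", format(attr(profile, "center_density")))
  ), con)
  utils::write.table(
    data.frame(z = sprintf("%.12g", profile$z),
               rho = sprintf("%.8g", profile$rho)),
    con, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}
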