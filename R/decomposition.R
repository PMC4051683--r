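# Difference-density decomposition into mirrored Gaussian populations.
#
# Subtracting the absolute electron density of a reference bilayer from a
# peptide- or additive-containing bilayer isolates the added molecule's
# distribution along the bilayer normal (valid at low additive fractions
# where the lipid matrix is unperturbed).  The difference is decomposed
# into mirrored Gaussian components; each component's integrated area
# times the area per lipid gives its electron count, and the counts give
# the population fractions of the molecular states (interface-bound,
# head-group-bound, membrane-embedded).

#' Difference electron-density profile
#'
#' Resamples both absolute profiles onto a common uniform grid over the
#' half-period \[0, min(d)/2\] and returns the pointwise difference
#' sample - reference.  Mismatched d-spacings are truncated to the
#' smaller half-period with a warning.
#'
#' @param sample,reference Absolute `density_profile`s.
#' @param n Grid points (default 512).
#' @return A data.frame of class `difference_profile` with columns `z`,
#'   `drho`.
#' @export
difference_profile <- function(sample, reference, n = 512) {
  for (p in list(sample, reference))
    if (!inherits(p, "density_profile") || p$scale_state != "absolute")
      stop("both profiles must be absolute-scaled density_profile objects")
  if (abs(sample$d_spacing - reference$d_spacing) >
      1e-6 * reference$d_spacing)
    warning("d-spacings differ (", sprintf("%.2f", sample$d_spacing),
            " vs ", sprintf("%.2f", reference$d_spacing),
            " A); truncating to the smaller half-period")
  zmax <- min(sample$d_spacing, reference$d_spacing) / 2
  z <- seq(0, zmax, length.out = n)
  ds <- stats::approx(sample$z, sample$rho, xout = z)$y
  dr <- stats::approx(reference$z, reference$rho, xout = z)$y
  out <- data.frame(z = z, drho = ds - dr)
  class(out) <- c("difference_profile", "data.frame")
  out
}

# Evaluate a mirrored-Gaussian mixture at z (centers >= 0; each component
# has an implied partner at -center contributing through its tail).
.mirrored_mix <- function(z, center, sigma, amplitude) {
  out <- numeric(length(z))
  for (i in seq_along(center)) {
    out <- out + amplitude[i] *
      (exp(-(z - center[i])^2 / (2 * sigma[i]^2)) +
       exp(-(z + center[i])^2 / (2 * sigma[i]^2)))
  }
  out
}

#' Fit mirrored Gaussian components to a difference profile
#'
#' Nonlinear least squares of a sum of k mirrored Gaussians (each with a
#' partner at -center, as required by the centrosymmetry of the lamellar
#' stack).  Fits are multistarted from center layouts spaced over the
#' half-period; the best converged start wins (ties broken by smaller
#' summed |center|).  Amplitudes may be negative, describing electron
#' deficits.
#'
#' @param diff A `difference_profile` (columns `z`, `drho`).
#' @param k Number of components per leaflet, 1..6.
#' @param A_L Area per lipid, Angstrom^2 (for electron counts).
#' @param n_starts Number of multistart layouts (default 8).
#' @param sigma_bounds Two-element bounds on component widths, Angstrom.
#' @return An object of class `component_model`: data.frame `components`
#'   (center desc, sigma, amplitude, electrons, fraction), `A_L`,
#'   `residual_rms`.
#' @export
fit_components <- function(diff, k, A_L, n_starts = 8,
                           sigma_bounds = c(0.5, 15)) {
  stopifnot(inherits(diff, "difference_profile"))
  if (k < 1 || k > 6) stop("k must be between 1 and 6")
  z <- diff$z; y <- diff$drho
  zmax <- max(z)
  amp0 <- max(abs(y))
  if (amp0 == 0) stop("difference profile is identically zero")
  best <- NULL
  starts <- lapply(seq_len(n_starts), function(s) {
    # quantile-spaced center layouts, jittered deterministically by start
    base <- zmax * (seq_len(k) - 0.5) / k
    shift <- zmax * (s - 1) / (2 * k * n_starts)
    pmin(pmax(base + shift, 0), zmax)
  })
  # one extremum-informed layout: centers at the k strongest local
  # extrema of the profile (padded with quantile positions)
  iext <- which(abs(diff(sign(diff(y)))) == 2) + 1L
  if (length(iext)) {
    iext <- iext[order(-abs(y[iext]))]
    ctrs <- z[utils::head(iext, k)]
    if (length(ctrs) < k)
      ctrs <- c(ctrs, zmax * (seq_len(k - length(ctrs)) - 0.5) / k)
    starts[[length(starts) + 1L]] <- sort(ctrs)
  }
  for (ctr0 in starts) {
    a0 <- stats::approx(z, y, xout = ctr0, rule = 2)$y
    a0[a0 == 0] <- 0.1 * amp0
    start <- c(ctr0, rep(zmax / (2 * k + 2), k), a0)
    names(start) <- c(paste0("c", 1:k), paste0("s", 1:k), paste0("a", 1:k))
    lower <- c(rep(0, k), rep(sigma_bounds[1], k), rep(-Inf, k))
    upper <- c(rep(zmax, k), rep(sigma_bounds[2], k), rep(Inf, k))
    fn <- function(p) {
      .mirrored_mix(z, p[1:k], p[(k + 1):(2 * k)], p[(2 * k + 1):(3 * k)]) - y
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = fn,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- sum(fit$fvec^2)
    cand <- list(par = fit$par, rss = rss)
    if (is.null(best) || rss < best$rss - 1e-12 * (1 + best$rss) ||
        (abs(rss - best$rss) <= 1e-12 * (1 + best$rss) &&
         sum(abs(cand$par[1:k])) < sum(abs(best$par[1:k]))))
      best <- cand
  }
  if (is.null(best)) stop("no multistart converged; cannot fit components")
  p <- best$par
  comp <- data.frame(center = p[1:k],
                     sigma = p[(k + 1):(2 * k)],
                     amplitude = p[(2 * k + 1):(3 * k)])
  comp$electrons <- mapply(component_electrons, comp$amplitude, comp$sigma,
                           MoreArgs = list(A_L = A_L))
  comp <- comp[order(-comp$center), ]
  rownames(comp) <- NULL
  comp$fraction <- population_fractions(comp$electrons)
  structure(list(components = comp, A_L = A_L,
                 residual_rms = sqrt(best$rss / length(z))),
            class = "component_model")
}

#' @export
print.component_model <- function(x, ...) {
  cat("<component_model> ", nrow(x$components), " mirrored components, ",
      "A_L = ", x$A_L, " A^2, residual rms = ",
      signif(x$residual_rms, 3), "\n", sep = "")
  print(x$components, digits = 4)
  invisible(x)
}

#' Electrons in one mirrored Gaussian component (per leaflet)
#'
#' N = A_L * |amplitude| * sigma * sqrt(2*pi): the component's integrated
#' density over its own leaflet times the in-plane area per lipid
#' column.  The mirrored partner belongs to the opposite leaflet and is
#' not double-counted.
#'
#' @param amplitude Component amplitude, e/A^3 (sign ignored).
#' @param sigma Gaussian width, Angstrom.
#' @param A_L Area per lipid, Angstrom^2.
#' @return Electron count.
#' @examples
#' component_electrons(0.013, 3.1, 60.6)  # ~6.1 e-
#' @export
component_electrons <- function(amplitude, sigma, A_L) {
  stopifnot(A_L > 0, sigma > 0)
  A_L * abs(amplitude) * sigma * sqrt(2 * pi)
}

#' Population fractions from electron counts
#'
#' @param electron_counts Numeric vector of per-component electrons.
#' @return Percentages summing to 100.
#' @examples
#' population_fractions(c(17.2, 17.7, 16.0, 7.2))
#' @export
population_fractions <- function(electron_counts) {
  if (!length(electron_counts) || all(electron_counts == 0))
    stop("at least one positive electron count is required")
  if (any(electron_counts < 0)) stop("electron counts must be non-negative")
  100 * electron_counts / sum(electron_counts)
}

#' Fraction of the population embedded below a depth boundary
#'
#' Components whose centers lie below `boundary_z` (toward the bilayer
#' center) are counted as membrane-embedded; the rest are
#' head-group-bound or interfacial.
#'
#' @param model A `component_model`, or a data.frame with columns
#'   `center` and `electrons`.
#' @param boundary_z Depth boundary, Angstrom (0 < boundary < d/2).
#' @return Percentage of electrons in embedded components.
#' @export
embedded_fraction <- function(model, boundary_z) {
  comp <- if (inherits(model, "component_model")) model$components else model
  stopifnot(boundary_z > 0, all(c("center", "electrons") %in% names(comp)))
  fr <- population_fractions(comp$electrons)
  sum(fr[comp$center < boundary_z])
}

#' Read/write component tables as delimited text
#'
#' Tables mirror the layout label/position/width/amplitude/electrons/
#' fraction.
#'
#' @param model A `component_model`.
#' @param path File path.
#' @param labels Optional component labels.
#' @return `write_component_table` returns the path;
#'   `read_component_table` returns a data.frame.
#' @export
write_component_table <- function(model, path, labels = NULL) {
  comp <- model$components
  df <- data.frame(
    label = if (is.null(labels)) seq_len(nrow(comp)) else labels,
    position = comp$center, width = comp$sigma,
    amplitude = comp$amplitude, electrons = comp$electrons,
    fraction = comp$fraction)
  utils::write.table(format(df, digits = 6), path, quote = FALSE,
                     row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_component_table
#' @export
read_component_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
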