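# Sign (phase) assignment for centrosymmetric bilayer form factors.
#
# A centrosymmetric electron-density profile has real form factors, so the
# crystallographic phase problem reduces to choosing nu_n = +/-1 per
# order.  Sampling theory gives a continuous form factor T(q_z) through
# the discrete |F_n|; measuring the same bilayer at several d-spacings
# ("swelling") samples T at different points, and an exhaustive search
# over sign vectors finds the assignment consistent across spacings.

#' Continuous form factor from a signed form-factor set
#'
#' The sampling expansion of the bilayer transform through its Bragg
#' samples.  Because a centrosymmetric profile has an even, real
#' transform, each order contributes a symmetric pair of interpolation
#' kernels:
#' T(q_z) = sum_n nu_n |F_n| \[sinc(q_z d/2 - pi n) +
#' sinc(q_z d/2 + pi n)\], with sinc(x) = sin(x)/x, sinc(0) = 1.  At the
#' Bragg positions q_m = 2 pi m/d of the same set every kernel except
#' the m-th vanishes, so T(q_m) = nu_m |F_m| exactly (the sampling
#' property), and T(0) = 0 when only orders n >= 1 are observed.
#'
#' @param ffset A `form_factor_set` with all signs assigned.
#' @param q_z Scattering vector(s), Angstrom^-1.
#' @return Numeric vector T(q_z).
#' @export
continuous_form_factor <- function(ffset, q_z) {
  stopifnot(inherits(ffset, "form_factor_set"))
  if (anyNA(ffset$sign))
    stop("all signs must be assigned before evaluating T(q_z)")
  d <- ffset$d_spacing
  sincf <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  vapply(q_z, function(q) {
    sum(ffset$sign * ffset$magnitude *
          (sincf(q * d / 2 - pi * ffset$order) +
           sincf(q * d / 2 + pi * ffset$order)))
  }, numeric(1))
}

# All 2^N sign vectors as an N x 2^N matrix of +/-1.
.sign_grid <- function(N) {
  if (N > 16) stop("exhaustive sign search is limited to 16 orders")
  m <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), N)))
  t(m)
}

#' Assign form-factor signs by the swelling method
#'
#' Requires form-factor sets measured at two or more distinct d-spacings.
#' One reference set (largest d by default, the densest q_z sampling) is
#' given a candidate sign vector, its continuous transform T is evaluated
#' at every other set's Bragg positions, and the candidate minimizing the
#' summed squared magnitude misfit sum (|T(q_n)| - |F_n|)^2 (weighted by
#' counting errors when supplied) wins.  T and -T fit identically, so
#' the search is over a global-flip quotient; the flip is then fixed by
#' the bilayer convention that the synthesized relative profile has its
#' minimum (the methyl trough) at the bilayer center.
#'
#' @param ffsets List of >= 2 `form_factor_set`s at distinct d-spacings.
#' @param reference Index of the reference set; default = largest d.
#' @param weights Optional list (parallel to `ffsets`) of per-order
#'   weights for the misfit.
#' @return A list of class `sign_assignment`: `signs` (integer vector
#'   over the reference set's orders), `ffset` (reference set with signs
#'   applied), `misfit`, `degenerate` (flag), `ranking` (misfit of all
#'   candidates, flip-quotiented).
#' @export
assign_signs <- function(ffsets, reference = NULL, weights = NULL) {
  stopifnot(is.list(ffsets), length(ffsets) >= 1)
  if (length(ffsets) == 1)
    stop("the swelling method needs >= 2 d-spacings; ",
         "supply signs explicitly for single-spacing data")
  ds <- vapply(ffsets, function(f) f$d_spacing, numeric(1))
  if (min(stats::dist(ds)) / max(ds) < 0.005)
    stop("d-spacings closer than 0.5% are degenerate for swelling analysis")
  if (is.null(reference)) reference <- which.max(ds)
  ref <- ffsets[[reference]]
  N <- length(ref$order)
  if (N == 1) {
    warning("single order: both signs fit equally; applying the ",
            "convention nu_1 = -1")
    signed <- form_factor_set(ref$d_spacing, ref$order, ref$magnitude, -1L)
    return(structure(list(signs = -1L, ffset = signed, misfit = 0,
                          degenerate = TRUE, ranking = NULL),
                     class = "sign_assignment"))
  }
  grid <- .sign_grid(N)
  # keep one representative per global-flip pair: first sign fixed to -1
  grid <- grid[, grid[1, ] == -1L, drop = FALSE]
  others <- ffsets[-reference]
  w_oth <- if (is.null(weights)) NULL else weights[-reference]
  # Interpolation details: (i) only points inside the reference sampling
  # band are used -- beyond the highest reference q the sinc series would
  # extrapolate; (ii) because T is even in q, the interpolant includes
  # the mirrored terms sinc(qd/2 + pi n); (iii) the unobservable n = 0
  # coefficient (the mean density contrast) is treated as a nuisance
  # parameter fitted per candidate.  At the Bragg nodes all extra terms
  # vanish, so the sampling identity of T is untouched.
  q_max <- max(ref$q)
  d <- ref$d_spacing
  sincf <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  pts <- list(); wts <- list(); mags <- list()
  for (j in seq_along(others)) {
    o <- others[[j]]
    inb <- o$q <= q_max * (1 + 1e-9)
    if (!any(inb)) next
    k <- length(pts) + 1L
    pts[[k]] <- o$q[inb]
    mags[[k]] <- o$magnitude[inb]
    wj <- if (is.null(w_oth)) rep(1, length(o$q)) else w_oth[[j]]
    wts[[k]] <- wj[inb]
  }
  qq <- unlist(pts); mm <- unlist(mags); ww <- unlist(wts)
  if (!length(qq))
    stop("no cross-evaluation points inside the reference sampling band")
  # basis: rows = evaluation points, cols = orders (+ the n = 0 column)
  B <- outer(qq, ref$order, function(q, n)
    sincf(q * d / 2 - pi * n) + sincf(q * d / 2 + pi * n))
  s0 <- sincf(qq * d / 2)
  c0_scale <- max(ref$magnitude)
  misfits <- apply(grid, 2, function(sg) {
    fixed <- as.vector(B %*% (sg * ref$magnitude))
    mis <- function(c0) sum(ww * (abs(fixed + c0 * s0) - mm)^2)
    c0g <- seq(-4, 4, length.out = 81) * c0_scale
    best0 <- c0g[which.min(vapply(c0g, mis, numeric(1)))]
    stats::optimize(mis, lower = best0 - 0.2 * c0_scale,
                    upper = best0 + 0.2 * c0_scale)$objective
  })
  best <- which.min(misfits)
  degenerate <- sum(abs(misfits - misfits[best]) <
                      1e-9 * (1 + misfits[best])) > 1
  if (degenerate)
    warning("sign search is degenerate: multiple sign vectors fit equally")
  signs <- as.integer(grid[, best])
  # fix the global flip: methyl trough (profile minimum) at z = 0
  rho0 <- sum(signs * ref$magnitude)          # ~ rho*(0) up to 2/d
  rho_edge <- sum(signs * ref$magnitude * cos(pi * ref$order))
  if (rho0 > rho_edge) signs <- -signs
  signed <- form_factor_set(ref$d_spacing, ref$order, ref$magnitude, signs)
  structure(list(signs = signs, ffset = signed, misfit = misfits[best],
                 degenerate = degenerate, ranking = misfits),
            class = "sign_assignment")
}

#' Apply user-supplied signs to a form-factor set
#'
#' For samples measured at a single d-spacing the swelling method does
#' not apply and signs must be provided (e.g. from a run configuration).
#'
#' @param ffset A `form_factor_set`.
#' @param signs Integer vector of -1/+1, one per observed order.
#' @return The signed `form_factor_set`.
#' @export
apply_signs <- function(ffset, signs) {
  if (length(signs) != length(ffset$order))
    stop("need one sign per observed order (",
         length(ffset$order), ")")
  form_factor_set(ffset$d_spacing, ffset$order, ffset$magnitude,
                  as.integer(signs))
}
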