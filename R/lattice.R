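# In-plane lattice analysis.
#
# Two in-plane structures matter for these membranes: the hexagonal
# (planar group p6) packing of gel-phase acyl chains, whose correlation
# peak position gives the chain-chain distance and area per lipid, and
# the monoclinic 2-D lattice of crystalline cholesterol plaques, whose
# [110] and [200] reflections index on a = 9.76 A, b = 7.56 A,
# gamma = 103 degrees.

#' Construct a 2-D oblique lattice
#'
#' @param a,b Lattice constants, Angstrom.
#' @param gamma Cell angle in degrees, 0 < gamma < 180.
#' @return An object of class `lattice2d`.
#' @export
lattice2d <- function(a, b, gamma) {
  stopifnot(a > 0, b > 0, gamma > 0, gamma < 180)
  structure(list(a = a, b = b, gamma = gamma), class = "lattice2d")
}

#' Reciprocal-space magnitude of an (h, k) reflection
#'
#' q_hk = (2*pi/sin(gamma)) * sqrt(h^2/a^2 + k^2/b^2
#'          - 2*h*k*cos(gamma)/(a*b)).
#'
#' @param lattice A `lattice2d`.
#' @param h,k Integer Miller indices, not both zero (vectorized).
#' @return q in Angstrom^-1.
#' @examples
#' reciprocal_q(lattice2d(9.76, 7.56, 103), 1, 1)  # ~1.19
#' reciprocal_q(lattice2d(9.76, 7.56, 103), 2, 0)  # ~1.32
#' @export
reciprocal_q <- function(lattice, h, k) {
  stopifnot(inherits(lattice, "lattice2d"))
  if (any(h == 0 & k == 0)) stop("(h, k) = (0, 0) has no reflection")
  g <- lattice$gamma * pi / 180
  (2 * pi / sin(g)) * sqrt(h^2 / lattice$a^2 + k^2 / lattice$b^2 -
                             2 * h * k * cos(g) / (lattice$a * lattice$b))
}

#' Fit 2-D lattice parameters to indexed reflections
#'
#' Least squares over the free parameters among {a, b, gamma}; the rest
#' are held at the values supplied in `fixed`.  Requires at least as
#' many observations as free parameters.
#'
#' @param observations Data.frame with columns `h`, `k`, `q`.
#' @param fixed Named list of fixed parameters, e.g.
#'   `list(gamma = 103)`.
#' @param start Optional named start values for the free parameters.
#' @return A fitted `lattice2d`.
#' @export
fit_lattice <- function(observations, fixed = list(), start = NULL) {
  stopifnot(all(c("h", "k", "q") %in% names(observations)))
  free <- setdiff(c("a", "b", "gamma"), names(fixed))
  if (nrow(observations) < length(free))
    stop("under-determined: ", nrow(observations), " observation(s) for ",
         length(free), " free parameter(s)")
  if (!length(free)) return(do.call(lattice2d, fixed[c("a", "b", "gamma")]))
  defaults <- c(a = 2 * pi / min(observations$q),
                b = 2 * pi / max(observations$q), gamma = 100)
  p0 <- defaults[free]
  if (!is.null(start)) p0[names(start)] <- unlist(start)
  obj <- function(p) {
    pars <- as.list(p); names(pars) <- free
    pars <- utils::modifyList(as.list(fixed), pars)
    if (pars$a <= 0 || pars$b <= 0 || pars$gamma <= 0 || pars$gamma >= 180)
      return(rep(1e6, nrow(observations)))
    lat <- lattice2d(pars$a, pars$b, pars$gamma)
    reciprocal_q(lat, observations$h, observations$k) - observations$q
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = obj,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  pars <- as.list(fit$par); names(pars) <- free
  pars <- utils::modifyList(as.list(fixed), pars)
  lattice2d(pars$a, pars$b, pars$gamma)
}

#' Area per lipid from the hexagonal chain-correlation peak
#'
#' Gel-phase acyl chains pack on a 2-D hexagonal net (planar group p6);
#' the observed wide-angle peak is its [10] reflection.  The chain-chain
#' (nearest-neighbour) distance is a_T = 2*pi/(q_T cos 30deg) and, with
#' two chains per lipid, the area per lipid is A_L = sqrt(3) * a_T^2.
#'
#' @param q_T Chain-correlation peak position, Angstrom^-1.
#' @return List with `a_T` (Angstrom) and `A_L` (Angstrom^2).
#' @examples
#' area_per_lipid_hex(1.49)  # a_T ~4.87, A_L ~41.1
#' @export
area_per_lipid_hex <- function(q_T) {
  stopifnot(q_T > 0)
  a_T <- 2 * pi / (q_T * cos(pi / 6))
  list(a_T = a_T, A_L = sqrt(3) * a_T^2)
}

#' Read/write in-plane peak tables
#'
#' Delimited text with columns label, position (A^-1), width, amplitude,
#' area.
#'
#' @param path File path.
#' @param table Data.frame with those columns.
#' @return `read_peak_table` returns the data.frame.
#' @export
read_peak_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
}

#' @rdname read_peak_table
#' @export
write_peak_table <- function(table, path) {
  utils::write.table(table, path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  invisible(path)
}

# Normalize a peak label: "[110]" -> "110".
.norm_label <- function(x) gsub("[^0-9a-zA-Z]", "", tolower(x))

.peak_area <- function(table, label) {
  i <- which(.norm_label(table$label) == .norm_label(label))
  if (!length(i)) stop("peak table is missing the '", label, "' row")
  sum(table$area[i])
}

#' Intensity change of cholesterol-plaque and chain peaks
#'
#' Computes the percentage change of the summed [110]+[200] monoclinic
#' areas and of the chain-correlation peak area between two in-plane
#' peak tables (e.g. before and after adding a peptide).  A growth of
#' the monoclinic areas indicates an increased volume fraction of
#' crystalline cholesterol plaques.
#'
#' @param before,after Peak tables (data.frames with columns `label`,
#'   `area`) containing rows labelled `110`, `200` and `chain`.
#' @return List with `monoclinic_pct` and `chain_pct`.
#' @export
plaque_intensity_change <- function(before, after) {
  mono_b <- .peak_area(before, "110") + .peak_area(before, "200")
  mono_a <- .peak_area(after, "110") + .peak_area(after, "200")
  ch_b <- .peak_area(before, "chain")
  ch_a <- .peak_area(after, "chain")
  list(monoclinic_pct = 100 * (mono_a - mono_b) / mono_b,
       chain_pct = 100 * (ch_a - ch_b) / ch_b)
}
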