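# Shared generators for the test suite.  Everything is built in code;
# randomness always goes through explicit seeds.

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Independent residue-composition oracle: explicit free-amino-acid count
# table, merged by plain arithmetic (kept separate from the package's
# formula objects on purpose).
oracle_residues <- list(
  G = c(C = 2, H = 5, N = 1, O = 2), A = c(C = 3, H = 7, N = 1, O = 2),
  S = c(C = 3, H = 7, N = 1, O = 3), P = c(C = 5, H = 9, N = 1, O = 2),
  V = c(C = 5, H = 11, N = 1, O = 2), T = c(C = 4, H = 9, N = 1, O = 3),
  C = c(C = 3, H = 7, N = 1, O = 2, S = 1), L = c(C = 6, H = 13, N = 1, O = 2),
  I = c(C = 6, H = 13, N = 1, O = 2), N = c(C = 4, H = 8, N = 2, O = 3),
  D = c(C = 4, H = 7, N = 1, O = 4), Q = c(C = 5, H = 10, N = 2, O = 3),
  K = c(C = 6, H = 14, N = 2, O = 2), E = c(C = 5, H = 9, N = 1, O = 4),
  M = c(C = 5, H = 11, N = 1, O = 2, S = 1), H = c(C = 6, H = 9, N = 3, O = 2),
  F = c(C = 9, H = 11, N = 1, O = 2), R = c(C = 6, H = 14, N = 4, O = 2),
  Y = c(C = 9, H = 11, N = 1, O = 3), W = c(C = 11, H = 12, N = 2, O = 2))

oracle_peptide_counts <- function(seq) {
  aa <- strsplit(seq, "")[[1]]
  tot <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (a in aa) {
    v <- oracle_residues[[a]]
    tot[names(v)] <- tot[names(v)] + v
  }
  tot["H"] <- tot["H"] - 2 * (length(aa) - 1)
  tot["O"] <- tot["O"] - (length(aa) - 1)
  tot[tot > 0]
}

# The reference DMPC/DMPS composition of the gel-state samples.
gel_composition <- function() {
  sp <- default_species()
  membrane_composition(
    lipids = list(list(species = sp$DMPC, fraction = 0.97),
                  list(species = sp$DMPS, fraction = 0.03)),
    waters_per_lipid = 7, area_per_lipid = 40.95,
    lamellar_spacing = 55.07)
}

# Mirrored-Gaussian difference profile with optional Gaussian iid noise.
make_difference <- function(truth, zmax = 27.5, n = 400, noise = 0,
                            seed = NULL) {
  z <- seq(0, zmax, length.out = n)
  y <- numeric(n)
  for (i in seq_len(nrow(truth)))
    y <- y + truth$amplitude[i] *
      (exp(-(z - truth$center[i])^2 / (2 * truth$sigma[i]^2)) +
       exp(-(z + truth$center[i])^2 / (2 * truth$sigma[i]^2)))
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + noise * max(abs(y)) * rnorm(n)
  }
  structure(data.frame(z = z, drho = y),
            class = c("difference_profile", "data.frame"))
}

# Helix-kink pseudo-atom model: two helical arms joined at an angle, an
# elongated asymmetric rigid body whose 1-D projection identifies its
# orientation (a single straight helix is nearly axially symmetric).
make_kinked_model <- function(s1 = "GSNKGAII", s2 = "GLMVGGVV",
                              bend = 120) {
  a1 <- make_helix_model(s1)$atoms
  a2 <- make_helix_model(s2)$atoms
  th <- bend * pi / 180
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  xyz <- as.matrix(a2[, c("x", "y", "z")]) %*% t(R)
  a2$x <- xyz[, 1] + 2
  a2$y <- xyz[, 2]
  a2$z <- xyz[, 3] + max(a1$z) + 1.5
  atomic_model(rbind(a1, a2), "helix-kink")
}

# Projection axis of a z-y-z pose in the body frame: the only angular
# quantity a 1-D projection can determine.
projection_axis <- function(angles) {
  b <- angles[2] * pi / 180
  g <- angles[3] * pi / 180
  c(-sin(b) * cos(g), sin(b) * sin(g), cos(b))
}

axis_angle_deg <- function(a1, a2) {
  acos(min(1, max(-1, sum(projection_axis(a1) * projection_axis(a2))))) *
    180 / pi
}

# Hand-written 3-atom PDB fixture text.
tiny_pdb_lines <- function() c(
  "HEADER    TEST FIXTURE",
  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
  "ATOM      3  O   GLY A   1       2.100   1.100   0.500  1.00  0.00           O",
  "END")

# Two-MODEL NMR-style fixture (second model shifted).
two_model_pdb_lines <- function() c(
  "MODEL        1",
  "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
  "ATOM      2  CA  ALA A   2       0.000   0.000   1.500  1.00  0.00           C",
  "ENDMDL",
  "MODEL        2",
  "ATOM      1  CA  ALA A   1       5.000   0.000   0.000  1.00  0.00           C",
  "ATOM      2  CA  ALA A   2       5.000   0.000   1.500  1.00  0.00           C",
  "ENDMDL",
  "END")
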