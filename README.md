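# memxrd

Analysis of X-ray diffraction from oriented multilamellar lipid
membranes: where do small peptides and additives sit inside a stacked
bilayer?

`memxrd` is for membrane biophysicists who measure specular
reflectivity and in-plane diffraction from solid-supported
multilamellar stacks (lipid bilayers with peptides, sterols or
hormones) and want to turn 1-D intensity curves into absolutely scaled
electron-density profiles, molecular population fractions, and
rigid-body positions of known atomic structures in the bilayer.

## The method

A multilamellar stack with repeat distance *d*<sub>z</sub> produces
Bragg peaks at *q*<sub>n</sub> = 2π*n*/*d*<sub>z</sub>. Each observed
order is fit by a Gaussian on a local linear background; the
Lorentz-corrected magnitudes |*F*<sub>n</sub>| = √(*I*<sub>n</sub>
*q*<sub>n</sub>) are the Fourier amplitudes of the bilayer profile.
Because the profile is centrosymmetric, each *F*<sub>n</sub> is real
and carries only an unknown sign ν<sub>n</sub> = ±1; the signs are
assigned by the swelling method — measuring the same bilayer at two or
more hydration states and exhaustively searching the 2<sup>N</sup>
sign vectors for the one whose continuous transform

> *T*(*q*<sub>z</sub>) = Σ<sub>n</sub> ν<sub>n</sub>|*F*<sub>n</sub>|
> [sinc(*q*<sub>z</sub>*d*/2 − π*n*) + sinc(*q*<sub>z</sub>*d*/2 + π*n*)]

is consistent across all states. The electron density over one period
is then the cosine series
ρ\*(z) = (2/*d*) Σ ν<sub>n</sub>|*F*<sub>n</sub>| cos(2π*n*z/*d*),
placed on an absolute e/Å³ scale by two physical conditions: a known
density at the bilayer center (0.22 e/Å³ for terminal CH₂/CH₃ groups,
up to 0.33 e/Å³ when amino acids fill the center) and electron
conservation — the profile integrated over the period times the area
per lipid must equal the electron content of two leaflets (e.g.
443.94 e⁻ per lipid for 97:3 DMPC:DMPS with 7 bound waters).

Differences between matched profiles (± peptide, ± additive) isolate
the added molecule's distribution and are decomposed into mirrored
Gaussian components; component areas × area-per-lipid give electron
counts and population fractions (interface-bound, head-group-bound,
membrane-embedded). Atomic structures (PDB) are projected into 1-D
densities with 4 Å FWHM Gaussian broadening, replicated across
leaflets and neighboring bilayers, and pose-fit (z-shift + rotation)
against the measured difference. In-plane curves give the hexagonal
chain-packing area per lipid (*a*<sub>T</sub> = 2π/(*q*<sub>T</sub>
cos 30°), *A*<sub>L</sub> = √3 *a*<sub>T</sub>²) and index crystalline
cholesterol-plaque reflections on a 2-D monoclinic lattice.

A seeded forward simulator (analytic Gaussian bilayer models with
closed-form form factors, Poisson counting noise) generates
ground-truth inputs for every stage, so the whole pipeline is
validated by round trips.

## Worked example

Simulate a gel-state bilayer stack, then run the full out-of-plane and
in-plane analysis:

```r
library(memxrd)

sp <- default_species()
comp <- membrane_composition(
  lipids = list(list(species = sp$DMPC, fraction = 0.97),
                list(species = sp$DMPS, fraction = 0.03)),
  waters_per_lipid = 7, area_per_lipid = 40.95, lamellar_spacing = 55.07)
leaflet_electron_budget(comp)
#> [1] 443.94

dir <- tempfile()
write_fixtures(dir, seed = 11)   # synthetic curves with known truth

cfg <- list(
  seed = 7,
  sample = list(lipids = list(DMPC = 0.97, DMPS = 0.03),
                waters_per_lipid = 7, area_per_lipid = 40.95),
  files = list(reflectivity = file.path(dir, "swelling_a.dat"),
               swelling = list(file.path(dir, "swelling_b.dat")),
               inplane = file.path(dir, "inplane_plaques.dat")),
  options = list(center_density = 0.22))
s <- run_pipeline(cfg, stages = c("peaks", "phase", "density", "inplane"),
                  output_dir = tempfile())
s$d_spacing    # 55.07    lamellar repeat, A (truth 55.07)
s$signs        # -1 -1 -1 -1  1 -1 -1  1   assigned sign vector
s$head_peak_z  # 21.83    head-group peak position, A (model: 22)
s$q_T          # 1.485    chain-correlation peak, A^-1 (truth 1.49)
s$a_T          # 4.885    chain-chain distance, A
```

Population arithmetic from a fitted component table (electron counts
per mirrored Gaussian):

```r
population_fractions(c(17.2, 17.7, 16.0, 7.2))
#> [1] 29.6 30.5 27.5 12.4          # percent of peptide electrons
embedded_fraction(data.frame(center = c(22, 17.6, 9, 4.3),
                             electrons = c(17.2, 17.7, 16, 7.2)), 14)
#> [1] 39.9                         # percent below the 14 A boundary
```

Cholesterol-plaque indexing:

```r
lat <- lattice2d(a = 9.76, b = 7.56, gamma = 103)
reciprocal_q(lat, 1, 1)   # 1.1906 A^-1  ([110])
reciprocal_q(lat, 2, 0)   # 1.3214 A^-1  ([200])
```

A thin command-line wrapper lives at `inst/cli/memxrd.R`
(`simulate`, `validate`, `run` subcommands over the same functions).

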