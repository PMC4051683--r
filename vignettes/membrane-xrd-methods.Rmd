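---
title: "Methods: from lamellar diffraction to peptide positions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from lamellar diffraction to peptide positions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memxrd)
```

This vignette is the package's own account of the science it
implements: the models, the assumptions behind them, the parameters
that matter, and the choices made where the design was genuinely open.

## The measurement and its model

Highly oriented multilamellar stacks of lipid bilayers diffract like a
1-D crystal along the stacking normal. With repeat distance $d_z$, the
specular reflectivity shows Bragg peaks at $q_n = 2\pi n/d_z$; up to
ten orders are resolvable for de-hydrated gel-state membranes, which
is why peptide localization is done in the gel state even though the
fluid state is the physiological one. The electron-density profile
over one period is reconstructed as a truncated cosine series

$$\rho^*(z) = \frac{2}{d}\sum_{n=1}^{N} \nu_n |F_n|
\cos\!\left(\frac{2\pi n z}{d}\right),$$

with $|F_n|$ the Lorentz-corrected Bragg amplitudes and
$\nu_n = \pm 1$ their signs. The model assumes a centrosymmetric,
laterally averaged bilayer — valid for symmetric stacks, and the
reason the phase problem degenerates to a sign problem.

### Peak fitting and the Lorentz correction

Each order is fit by a Gaussian plus a *local* linear background in a
window of $\pm 4$ expected widths around $n\,2\pi/d$ (the shape of the
diffuse background under a full curve is not modelled; locally linear
is an adequate and assumption-light description). Missing orders are
recorded as absent, not zero: the form factor genuinely oscillates
through zero, and a vanishing order carries no sign information.
Integrated intensities are converted by
$|F_n| = (I_n q_n)^{1/2}$, the single-$q$ Lorentz factor for oriented
stacks. Because conventions with exponent 1 exist in the literature
for other geometries, the exponent is exposed
(`lorentz_exponent`, default 0.5) and the forward simulator inverts
whichever convention is configured, so round trips are always
self-consistent.

### Sign assignment by swelling

Sampling theory connects the discrete amplitudes to a continuous
transform. Because the profile is even, its transform $T(q_z)$ is even
and real, and the interpolation through the Bragg samples uses a
symmetric kernel pair per order:

$$T(q_z) = \sum_n \nu_n |F_n| \left[
\mathrm{sinc}\!\left(\tfrac{q_z d}{2} - \pi n\right) +
\mathrm{sinc}\!\left(\tfrac{q_z d}{2} + \pi n\right)\right].$$

At the Bragg nodes of the same set every kernel but one vanishes
($T(q_m) = \nu_m|F_m|$, checked to $10^{-12}$ in the tests), and
$T(0) = 0$ when only orders $n \ge 1$ are observed.

`assign_signs()` exhaustively searches the $2^N$ sign vectors
($N \le 16$) for the reference set (largest $d$, i.e. densest $q$
sampling), scoring each candidate by the squared misfit between
$|T|$ evaluated at the other hydration states' Bragg positions and
their measured $|F_n|$, inverse-variance weighted when counting errors
exist. Three numerical details matter, found during validation and
now part of the method:

* **No extrapolation.** Points beyond the reference set's highest $q$
  are excluded — outside the sampled band the sinc series extrapolates
  and its values are meaningless.
* **The unobservable $n=0$ term.** The mean density contrast
  $F_0$ is not measurable in this geometry but its interpolation
  kernel leaks into the band. It is fitted per candidate as a
  nuisance parameter (coarse grid plus 1-D refinement).
* **The global flip.** $T$ and $-T$ fit identically, always. The
  quotient is searched (first sign pinned), and the flip is fixed by
  the bilayer convention that the synthesized profile has its minimum
  — the terminal-methyl trough — at the bilayer center. With a single
  observed order both signs fit equally; the convention
  $\nu_1 = -1$ is applied with a warning.

With these choices, sign recovery on simulated swelling triplets
($d$ = 55.07, 60, 65 Å, 8 orders, 1% amplitude noise) is 100% over 50
seeds. For samples measured at a single hydration state signs must be
supplied explicitly (`apply_signs()`, or `options$signs` in a run
config); no algorithm can recover them from one spacing.

### Absolute scaling

The synthesized profile is known only up to an affine map
$\rho \mapsto \alpha\rho^* + \beta$. Two conditions determine it:

1. $\rho(0)$ equals a known center density — 0.22 e/Å³, the electron
   density of terminal CH~2~/CH~3~ groups, for a lipid-only gel
   bilayer. When a peptide may occupy the center, the appropriate
   value lies between 0.22 and 0.33 e/Å³ (the mean amino-acid
   density); since the choice is not determined by the diffraction
   data alone, `scale_to_absolute()` takes it as an explicit argument
   and a scan over the range with an agreement score against a
   structure calculation is the intended workflow.
2. Electron conservation:
   $A_L \int_{-d/2}^{d/2} \rho\, dz = 2B$, where $B$ is the per-lipid
   electron budget of one leaflet from the sample composition
   (e.g. $0.97\cdot374 + 0.03\cdot372 + 7\cdot10 = 443.94$ e⁻ for
   97:3 DMPC:DMPS with 7 bound waters at 50% RH; 25 waters per lipid
   is the fully hydrated default).

Because the cosine series integrates to zero over a full period, the
system is linear and solves in closed form; $\alpha > 0$ is enforced
(a negative solution means the sign convention was flipped and is
corrected with a warning). Conservation after scaling holds to 0.1%
on all grids of at least 512 points (trapezoidal rule; default grid
1024 points, at least 4 per observed order).

## Difference densities and populations

Subtracting a matched reference profile isolates an added molecule's
distribution. This assumes the lipid matrix is unperturbed by the
addition, which holds at the 3 mol% peptide fractions used here but
would fail at higher loadings. Mismatched periods are truncated to
the smaller half-period with a warning.

The difference is decomposed into $k \le 6$ mirrored Gaussian
components (each with an implied partner at $-z$, as centrosymmetry
requires). The fit is multistarted from quantile-spaced center
layouts plus one extremum-informed layout; ties are broken by the
smaller summed $|$center$|$. Electrons per component are
$N_i = A_L\,|a_i|\,\sigma_i\sqrt{2\pi}$, counted once per leaflet (the
mirror partner belongs to the opposite leaflet). Tabulated component
widths in this field are treated as Gaussian $\sigma$ — the
convention that reproduces published per-component electron counts
within 1% where they are reproducible at all. Population fractions
are percentages of the summed electrons, and the embedded fraction
sums components whose centers lie below a depth boundary (between the
head-group region and the hydrocarbon core, typically ~14 Å for a
gel-state phosphatidylcholine bilayer).

On simulated 4-component differences with 2% noise, the median center
error is below 0.5 Å and the median electron error below 5% across 25
seeds.

## Projecting atomic structures and fitting poses

Solution NMR structures (PDB files; first MODEL of multi-model
entries) are projected to 1-D by broadening each atom with a Gaussian
of FWHM 4 Å — an empirical stand-in for thermal motion — weighted by
its atomic number. Hydrogens are included when present; a
heavy-atom-only mode exists because deposited structures vary in
whether they include them. The projected integral equals the total
electron count under every pose (conservation to 0.01%, grid extended
4σ beyond the extreme atoms).

The measured difference density is symmetric and periodic, so the
calculated profile adds the mirrored leaflet partner and images from
neighboring bilayers before comparison. The pose (z-shift plus z–y–z
Euler rotation about the centroid) is found by exhaustive grid search
— 0.5 Å and 15° defaults keep a desk-scale runtime — optionally with
one free non-negative amplitude scale absorbing the unknown
molecule-per-lipid stoichiometry.

Two identifiability facts shape how pose recovery is validated:

* A 1-D projection determines the rotation only through the
  *projection axis* (a point on the sphere parametrized by the second
  and third Euler angles); the first Euler angle never changes the
  profile and is reported as the grid's first value.
* For an off-grid true pose, the best *grid* pose in least-squares
  score can legitimately sit more than one grid step from the truth
  componentwise, because the score landscape on the sphere is shallow
  after 4 Å broadening. The recovery property is therefore stated
  against the identifiable reference: the z-shift must land within
  one grid step of the truth, and the angles within one grid step of
  the noiseless grid optimum, across seeds. An ideal straight helix
  is nearly axially symmetric (its azimuth is unidentifiable in
  principle), so validation uses a kinked two-arm helix, which is
  also the shape these membrane-active peptides actually adopt.

Degenerate fits (distinct rotations tying at the optimum, e.g. for
spherically symmetric models) are flagged and tie-broken
deterministically: smaller $|z|$, then lexicographic angles.

## In-plane analysis

Gel-phase acyl chains pack on a 2-D hexagonal net (planar group p6);
the wide-angle correlation peak near 1.5 Å⁻¹ is its [10] reflection.
The chain–chain distance is $a_T = 2\pi/(q_T\cos 30°)$ and the area
per lipid $A_L = \sqrt3\,a_T^2$ (two chains per lipid). This
convention — rather than the naive $2\pi/q$ — is what reproduces
tabulated tail spacings, and the algebraic identity
$A_L q_T^2 = 16\pi^2/\sqrt3$ is tested exactly. In the fluid phase
the peak is too fluctuation-broadened for this to be quantitative; a
literature fluid-phase area (60.6 Å² for DMPC) is used instead.

Crystalline cholesterol plaques coexisting with the lamellar phase
contribute extra in-plane reflections indexed on an oblique 2-D
lattice,
$q_{hk} = \frac{2\pi}{\sin\gamma}\sqrt{h^2/a^2 + k^2/b^2 -
2hk\cos\gamma/(ab)}$, with $a = 9.76$ Å, $b = 7.56$ Å,
$\gamma = 103°$ placing [110] at 1.19 Å⁻¹ and [200] at 1.32 Å⁻¹.
Growth of the summed [110]+[200] areas between paired measurements
quantifies plaque-fraction changes; the chain-peak change is reported
alongside. On the published peak areas the monoclinic growth after
peptide addition is +29.2% (quoted as 30%), while the chain-peak
change computes to −54.6% from the same table even though −65% is
quoted in the text — the discrepancy is surfaced, not hidden.

## The forward simulator

`bilayer_model()` describes a bilayer as mirrored Gaussians on a
water background; the default gel model places head groups at ±22 Å
(σ = 3 Å) and a negative methyl trough at the center (σ = 2.5 Å),
matching the qualitative gel-state profile, with $d$ = 55.07 Å and
area 40.95 Å² as the gel-state study conditions. Its form factors
have a closed form, intensities follow by inverting the Lorentz step
with Gaussian line shapes and a linear background, and counting noise
is Poisson: `noise_scale = 1` draws plain Poisson counts at the
simulated rate (≈1% relative noise at the default count scale),
`0` is noiseless, and other values rescale the relative fluctuation
through an adjusted gain. All randomness flows through explicit
seeds; identical seeds give byte-identical fixture packs.

What the simulator deliberately does **not** emulate: instrument
resolution and beam footprint, absorption, mosaic spread, diffuse
scattering from fluctuations, and the reduction of 2-D detector
images to 1-D cuts (inputs are already 1-D). Passing round-trip tests
therefore demonstrates the correctness of the analysis chain, not
robustness to every artifact of real detectors. Two further
idealizations matter for sharp numerical claims: the closed-form
factors are whole-line Gaussian transforms, so models whose tails
cross the half-period carry a small aliasing difference from the
periodized profile (~1–2% for the default gel model, which the ≤2%
round-trip bound absorbs); and the interpolated transform is exact
only for zero-mean, compactly supported profiles, the conditions
under which the 1% accuracy test is stated.

Full-pipeline round trips (model → form factors → noisy curves → peak
fit → Lorentz → sign search → synthesis → absolute scaling) recover
the model density with relative L2 error below 2% at 10 orders with
counting noise, and below 10% at 4 orders, where truncation
dominates.

## Electron bookkeeping

Species are defined by chemical formula; electron counts are exact
sums of atomic numbers and molar masses use IUPAC values to three
decimals. Peptides are treated as neutral chains with free termini:
the formula is the sum of free amino-acid formulas minus one water
per bond. No protonation states, isotopes or modifications are
modelled. Two published bookkeeping inconsistencies are handled
explicitly rather than silently adopted: the 11-residue fragment's
tabulated 678 e⁻ conflicts with its own formula and mass
(C₄₅H₈₁N₁₃O₁₄S, 570 e⁻, 1060.3 g/mol) — the formula value is used and
requesting the tabulated one warns; and DMPS is registered in the
protonated form (372 e⁻), consistent with its tabulated electron
count, while the tabulated 701.8 g/mol (the sodium salt) is kept as a
molar-mass override.

## Problem sizes and reproducibility

The validation suite runs at the scales the method is used at:
10-order reflectivity curves of 4000 points, swelling triplets with 8
orders, 50 seeds for sign recovery, 25 for decomposition, 10 for pose
recovery on a 27 z-step × 13 × 24 angle grid — a few minutes in
total on one core. Every stochastic test fixes its seed; re-running
any pipeline stage with unchanged inputs and seeds reproduces its
outputs byte for byte.

## Known limitations

* Sign assignment needs at least two genuinely different d-spacings
  (>0.5% apart); single-state data require user-supplied signs.
* The center-density condition for peptide-containing samples is an
  external physical choice, scanned rather than inferred.
* Absolute population fractions rest on tabulated electron counts
  where published Gaussian parameters are internally inconsistent;
  fractions are robust to this, absolute electron numbers are not.
* Pose fitting is rigid-body only — no conformational refinement, no
  β-sheet modelling — and its angular resolution is intrinsically
  limited by the 1-D projection and the 4 Å broadening.
* In the presence of coexisting lateral phases (cholesterol plaques)
  the 1-D profile is a superposition and single-molecule positions
  are not recoverable; the package reports in-plane quantities for
  that regime instead.
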