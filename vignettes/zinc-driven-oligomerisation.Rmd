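---
title: "Modelling zinc-driven oligomerisation of Histatin 5"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling zinc-driven oligomerisation of Histatin 5}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histazinc)
```

## The problem

Histatin 5 (Hst5) is a 24-residue, histidine-rich salivary peptide that
behaves as an intrinsically disordered protein in solution. In the presence
of Zn2+ it forms small, highly dynamic oligomers — mostly monomers, a few
percent dimers, traces of larger species — mediated by zinc coordination at
histidine-rich motifs: the canonical HExxH zinc motif (H15-E16-K17-H18-H19)
and a zinc-binding-like motif HAKRHH near the N-terminus (H3, H7, H8). This
package implements the computational side of that analysis: a coarse-grained
Monte Carlo model of the multi-chain solution with an implicit-zinc
attraction, plus the SAXS, PFG-NMR diffusion, and calorimetric analysis
stages, with synthetic-data generators standing in for the beamline and
spectrometer.

## The coarse-grained model

Each residue is a hard sphere of radius 2 Å; two extra terminal beads carry
the N-terminal (+1) and C-terminal (−1) charges, so a 24-mer peptide is a
26-bead chain. Consecutive beads are connected by harmonic bonds with
equilibrium length $r_0 = 4.1$ Å and force constant 0.4 N/m
(≈ 2.409 kJ/mol/Å²). Side-chain charges at pH 6.7 are −1 for Asp/Glu and +1
for Lys/Arg, with histidine neutral (pKa ≈ 6); `ph_mode = "protonated-his"`
models the pH 4 control in which histidines carry +1 and zinc-induced
association is abolished. The wild-type net charge is +5 (+12 with
protonated histidines).

Non-bonded bead pairs interact through

* a hard-sphere exclusion below contact (4 Å),
* an extended Debye–Hückel screened Coulomb term
  $u_{el}(r) = \frac{z_i z_j e^2}{4\pi\varepsilon_0\varepsilon_r}
  \frac{\exp[-\kappa(r - R_i - R_j)]}{(1+\kappa R_i)(1+\kappa R_j)}\,
  \frac1r$, with $\kappa$ computed from the ionic strength (150 mM by
  default, $1/\kappa \approx 7.9$ Å at 298 K, $\varepsilon_r = 78.4$), and
* a short-ranged dispersion-like attraction $-\epsilon_{ij}/r^6$.

Bonded neighbours keep the hard-sphere constraint but are excluded from the
electrostatic and $1/r^6$ sums; with $r_0$ barely above contact their
separation is dominated by the bond anyway.

### The implicit-zinc ("sticky") attraction

Zinc is not represented explicitly. Instead, the beads expected to
coordinate Zn2+ — all histidines, plus the motif glutamate E16 while the
HExxH motif is intact — form a "sticky" set whose per-bead interaction
strength is raised from the generic $\epsilon = 0.6\times10^4$ kJ Å⁶/mol
(0.6 kT at contact) to $3.0\times10^4$ kJ Å⁶/mol (3.0 kT at contact).
Per-bead strengths are combined by **arithmetic averaging**, so
sticky–sticky pairs attract with 3.0 kT at contact, generic pairs with
0.6 kT, and mixed pairs with the mean, 1.8 kT. The model's short-ranged
term is an approximate arithmetic average of per-residue polarisability
strengths, which admits two readings of how a strengthened bead interacts
with an ordinary one; we adopted the mixing rule after testing both
alternatives: restricting the
strengthened attraction strictly to sticky–sticky pairs leaves the system
at ≈ 99.4% monomers for 16 wild-type chains in the 450 Å box, far from the
reported 94%, whereas arithmetic mixing reproduces the published cluster
populations at both ≈ 1 mg/mL (92–94% monomers) and 2.8 mg/mL (≈ 81–82%).
`energy_params(eps_cross = )` exposes the choice; passing `eps_generic`
restores the strict rule.

Sticky attraction acts on intra- and inter-chain pairs alike (monomer
compaction and oligomerisation are both observed), and is simply absent
when `zinc_present = FALSE` or in the histidine-free variant.

### Variants

The exact variant sequences are encoded from their design descriptions with
histidine→glutamine substitutions (glutamine being a pH-insensitive
histidine analogue of similar size): `DZM` removes the zinc-motif
histidines (H15, H18, H19); `ZM` removes H3, H7, H8 and additionally H21 so
that three histidines remain, as tabulated; `2H` keeps only H7 and H18;
`DH` removes all seven. `RAN` is a fixed, documented permutation of the
wild-type composition (`HKRHGYSHKDHAFHEKHRYKSHRG`) with seven histidines
and no intact HExxH motif. Where a variant breaks the HExxH motif, E16
leaves the sticky set. Which specific histidines `2H` retains and the exact
randomised order are not published; the choices here are fixed and
documented rather than inferred.

## Monte Carlo sampling

Sampling is canonical (NVT) Metropolis Monte Carlo at 298 K in a cubic
periodic box, with minimum-image distances. One *pass* is one trial move
per bead. Four move types run in the attempt ratio 20 : 1 : 1 : 1:

* **single-bead** displacement, uniform in a cube;
* **pivot**: the shorter tail of a chain is rigidly rotated about a random
  axis through a random internal bead;
* **chain translation** of a whole chain;
* **slither** (reptation): an end bead is removed and regrown at the other
  end with its bond length drawn from the bond Boltzmann density
  $p(\ell)\propto \ell^2 e^{-U_{bond}(\ell)/kT}$ truncated at contact, so
  the regrown bond's energy cancels against the proposal density in the
  acceptance rule.

There is no single standard definition of the pivot angle distribution or
the slither regrowth rule; the uniform angle in $[-\theta_{max},
\theta_{max}]$ about a uniformly random axis and the bond-sampled regrowth
are this package's documented choices.

Displacement amplitudes are auto-tuned toward ≈ 30% acceptance during
equilibration only and frozen in production, preserving detailed balance.
Production is divided into subdivisions (ten by default) and every
observable's uncertainty is the standard deviation of the mean over
subdivision averages. Correctness is tested against independent oracles: a
brute-force all-pairs energy (1e-9 relative), exact equality of the
incremental energy bookkeeping with a full recompute, Boltzmann statistics
of a two-bead bond against numerical quadrature, and transitive-closure
clustering against a matrix-power oracle.

### Numerical choices

* **Interaction cutoff.** The published model truncates only by minimum
  image. For the large production boxes we apply a 60 Å cutoff to the
  non-bonded terms: at 150 mM the screened Coulomb term at 60 Å is below
  $10^{-4}$ kJ/mol and the $1/r^6$ term below $10^{-6}$ kJ/mol, both
  negligible against kT = 2.48 kJ/mol. All oracle-equivalence tests run
  with `cutoff = Inf` (pure minimum image).
* **Intra-chain distances** are evaluated without minimum-image folding
  whenever the largest possible chain extent plus the cutoff fits in the
  box, which is then exactly equivalent and faster.
* Chain-level bounding spheres cull distant chains from energy sums; the
  culling radius equals the cutoff, so it is exact, not approximate.
* Initial configurations are non-overlapping self-avoiding walks; an
  overlap-free placement failure after bounded retries is an error.

## Cluster (oligomer) analysis

Two chains are clustered when any bead–bead centre distance (minimum
image) is ≤ 6 Å; oligomers are the transitive closure of this relation.
The reported distribution is the percentage of *chains* in monomers,
dimers, trimers and tetramers-or-larger, and the number-average cluster
size $N_{ass}$ = (chains)/(clusters), averaged over frames with
subdivision errors. The 6 Å criterion is read as centre–centre distance:
the bead model has no other natural surface definition.

## Scattering and SAXS analysis

The orientationally averaged structure factor is computed by the Debye
double sum $S(q) = \frac1N \sum_{jk} \frac{\sin qr_{jk}}{qr_{jk}}$ — exact
for an isotropic ensemble — and validated against explicit direction
averaging of $|\sum_j e^{i\mathbf{q}\cdot\mathbf{r}_j}|^2$ on a Fibonacci
sphere. Guinier analysis fits $\ln I$ vs $q^2$ over a window iterated from
$qR_g \le 1.3$ down to $\le 0.8$; on the Debye coil form this carries a
known ≈ 2% systematic underestimate of $R_g$ even in that window, which is
why the recovery tolerance for coil curves is 3%. The model-comparison
$\chi^2$ is implemented exactly as defined — residuals relative to the
scaled simulated intensity, the scale matching forward intensities — with
a σ-weighted variant available but never the default. The mass fractal
dimension is minus the log-log slope over a configurable window
(0.05–0.2 Å⁻¹ by default; no canonical window exists). The
oligomerisation ratio $\beta = (I_{0,Zn}/c_{Zn})/(I_0/c)$ equals 1 for no
mass increase. Two printed table rows (`ZM`, `2H`) do not round-trip from
their own printed inputs at two decimals (1.54 vs 1.48 and 1.22 vs 1.21) —
presumably computed from unrounded data — so exactness is asserted only
for the four rows that do.

A note on Kratky representations: the dimensionless Kratky curve of a
*Gaussian coil* (Debye function) rises monotonically to a plateau of 2; it
is the compact/globular Guinier form $(qR_g)^2 e^{-(qR_g)^2/3}$ that peaks
at $qR_g = \sqrt3$ with height $3/e \approx 1.104$. The tests assert both
facts; the often-quoted "coil peak at √3" conflates the two.

## PFG-NMR diffusion

Peak decays follow the Stejskal–Tanner equation
$I = I_0\exp[-g^2\gamma^2\delta^2(\Delta - \delta/3)D]$ with δ = 2 ms and
Δ = 200 ms; fits are nonlinear least squares started from the log-linear
regression. Gradients are fractions of the instrument maximum (2–98% over
32 points); because the absolute calibration is instrument-specific and
not published, absolute D values depend on `g_max` (default 0.5 T/m,
giving realistic decay to ≈ 1% at full gradient for D ≈ 3×10⁻¹⁰ m²/s),
while hydrodynamic radii via the internal dioxane reference
($R_h = (D_{ref}/D_{prot})\cdot 2.12$ Å) are calibration-free and are the
primary output. Histograms of per-peak D values are fitted with a bounded
Gaussian least squares across several bin widths to check robustness.

## Thermodynamics

Zinc binding measured by titration calorimetry at 20 °C is kept as a
packaged record (`hst5_thermo()`): Kd of 26/45/61 µM for the wild type and
the two single-motif variants, with ΔG = ΔH + (−TΔS) reproduced exactly
and RT ln Kd at 293.15 K agreeing within the stated uncertainties plus
0.2 kJ/mol. The wild type binds enthalpically (compaction across both
motifs); the single-motif variants bind entropically (desolvation and
counter-ion release) — the package only checks this bookkeeping, it does
not fit raw injection heats.

## Synthetic data

`synth_saxs_curve()` builds Gaussian-coil (Debye) curves, optionally as
monomer/oligomer mixtures in which a fraction $f_s$ of chains resides in
s-mers: per unit chain concentration $I(q) \propto \sum_s f_s\, s\,
P(q; R_g s^{\nu})$ with ν = 0.5 (ideal-chain size scaling), so forward
scattering scales with mass exactly as the β analysis assumes.
`synth_pfg_dataset()` builds Stejskal–Tanner decays on the 32-point
gradient grid. Both add multiplicative Gaussian noise of configurable
relative level (no published noise characterisation exists to emulate;
multiplicative Gaussian is a simple stand-in) and are pure functions of
their arguments and seed. What passing recovery tests on these generators
shows is that the *analysis* stages are unbiased at realistic noise; they
do not emulate detector geometry, buffer subtraction or radiation damage,
so agreement with real beamline data is a separate question.

## Problem sizes used in validation

The reference production schedule is 2×10⁵ equilibration passes and 2×10⁶
production passes. The packaged validation runs use the same systems
(16 chains in a 450 Å box per 1 mg/mL; 45 chains at 2.8 mg/mL) at reduced
length — around 10⁴ equilibration and (2–5)×10⁴ production passes per
replica, pooled over 2–6 independent seeds. The monomer fraction
decorrelates slowly (bound dimers persist for thousands of passes), so at
fixed wall time pooling replicas shrinks its error faster than lengthening
one run; the pooled spread is one to two percentage points, small compared
with the population differences of interest. The concentration- and
stickiness-monotonicity checks run in a 200 Å box (4–24 chains) where
association is strong enough that the trend exceeds the sampling noise.

## Known limitations

* Implicit zinc cannot capture stoichiometry or saturation; the sticky
  strength is concentration-independent, so very high Zn2+:peptide ratios
  (where precipitation is observed experimentally) are outside the model.
* Electrostatics are Debye–Hückel level with a uniform dielectric; no
  polarisation, no explicit ions.
* The cluster criterion is geometric; lifetimes and exchange kinetics are
  not meaningful in Monte Carlo time.
* Absolute SAXS intensity scale and molecular weights from water
  calibration are out of scope; only concentration-normalised ratios are
  computed.

## A worked example

```{r example, eval = FALSE}
library(histazinc)

pep <- build_peptide("WT")
sys <- build_system(pep, box_length = 450, n_chains = 16,
                    zinc_present = TRUE, seed = 1)
run <- run_simulation(sys, energy_params(cutoff = 60),
                      mc_config(equilibration = 2e4, production = 4e4,
                                seed = 1, cluster_stride = 25))
oligomer_distribution(run)
tidy(run)

# SAXS side: beta from the measured table
tbl <- hst5_saxs_table()
dplyr::mutate(tbl, beta = beta_ratio(i0_zn, c_p_zn, i0, c_p))
```
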