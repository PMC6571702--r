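# histazinc

Coarse-grained simulation and scattering analysis of Zn²⁺-driven
oligomerisation of Histatin 5.

Histatin 5 (Hst5) is a 24-residue, histidine-rich salivary peptide — an
intrinsically disordered protein — that forms small, dynamic oligomers in
the presence of Zn²⁺ through zinc–histidine coordination at two motifs: the
canonical HExxH zinc motif (H15-E16-K17-H18-H19) and an N-terminal
zinc-binding-like motif HAKRHH. `histazinc` is for modellers and
biophysicists who want to reproduce, probe or extend the computational
analysis of that system: a multi-chain bead–spring Monte Carlo model with
implicit zinc, and the companion SAXS, PFG-NMR and calorimetric analysis
stages, all testable against synthetic data.

## The model in brief

Each residue is a hard sphere (radius 2 Å) plus two charged terminal beads;
consecutive beads share a harmonic bond (r₀ = 4.1 Å, k = 0.4 N/m). Charged
beads interact through an extended Debye–Hückel potential

  u_el(r) = z_i z_j e²/(4πε₀ε_r) · exp[−κ(r − R_i − R_j)] /
            [(1 + κR_i)(1 + κR_j)] / r,

and all non-bonded pairs attract as −ε/r⁶: ε = 0.6×10⁴ kJ Å⁶/mol between
ordinary beads (0.6 kT at contact) and 3.0×10⁴ kJ Å⁶/mol (3.0 kT) between
"sticky" beads — the histidines plus the motif glutamate — when Zn²⁺ is
present, with mixed pairs at the arithmetic mean. Metropolis Monte Carlo
(single-bead, pivot, chain-translation and reptation moves, weighted
20:1:1:1) samples the NVT ensemble; oligomers are chains linked by any
bead–bead contact ≤ 6 Å. The SAXS side implements Guinier fits (qR_g ≤
0.8), Kratky transforms, mass fractal dimensions, the χ² model comparison
and the oligomerisation ratio β = (I₀,Zn/c_Zn)/(I₀/c); the NMR side fits
Stejskal–Tanner decays and converts to hydrodynamic radii via the internal
dioxane reference (R_h,ref = 2.12 Å).

## A worked example

Sixteen wild-type chains in a 450 Å periodic box (≈ 1 mg/mL) with the
implicit-zinc attraction:

```r
library(histazinc)

pep <- build_peptide("WT")
pep
#> <peptide> WT: DSHAKRHHGYKRKFHEKHHSHRGY
#>   histidines: 7; sticky residues (with Zn2+): 3, 7, 8, 15, 16, 18, 19, 21

sys <- build_system(pep, box_length = 450, n_chains = 16,
                    zinc_present = TRUE, seed = 1)
run <- run_simulation(sys, energy_params(cutoff = 60),
                      mc_config(equilibration = 2e4, production = 4e4,
                                seed = 1, cluster_stride = 25))
oligomer_distribution(run)
#> # A tibble: 4 × 4
#>   species    size fraction_pct se_pct
#>   <chr>     <int>        <dbl>  <dbl>
#> 1 monomer       1       92.0   2.44
#> 2 dimer         2        7.88  2.41
#> 3 trimer        3        0.105 0.0369
#> 4 tetramer+     4        0     0
```

92% of chains are monomers and ~8% dimers, with a number-average cluster
size N_ass ≈ 1.04 — a dilute solution of transient dimers, matching the
reported simulated populations (94% monomers, 5.5% dimers at this
concentration at full production length). The overall move acceptance is
≈ 32%, and `tidy(run)` returns every observable (energy, mean R_g,
end-to-end distance, cluster fractions) with subdivision-based standard
errors.

The SAXS-side β arithmetic on the measured table:

```r
dplyr::mutate(hst5_saxs_table(),
              beta = round(beta_ratio(i0_zn, c_p_zn, i0, c_p), 2))
#> WT 2.63, RAN 1.96, DZM 1.39, ZM 1.54, 2H 1.22, DH 0.96
```

β declines from 2.63 (wild type, 7 His) to 0.96 (histidine-free): no
histidines, no zinc-driven mass increase.

## Package tour

| area | functions |
| --- | --- |
| model building | `hst5_variants()`, `build_peptide()`, `assign_charges()`, `sticky_set()`, `bead_chain()`, `build_system()` |
| energetics | `energy_params()`, `pair_energy()`, `bond_energy()`, `total_energy()`, `debye_kappa()` |
| simulation | `mc_config()`, `run_simulation()`, `propose_move()`, `metropolis_accept()`, `subdivision_error()` |
| trajectory analysis | `radius_of_gyration()`, `end_to_end()`, `find_clusters()`, `cluster_statistics()`, `oligomer_distribution()`, `structure_factor()` |
| SAXS | `scattering_curve()`, `guinier_fit()`, `chi_square()`, `beta_ratio()`, `fractal_dimension()`, `kratky_transform()`, `hst5_saxs_table()` |
| PFG-NMR | `pfg_dataset()`, `fit_stejskal_tanner()`, `fit_gaussian_histogram()`, `rh_from_diffusion()` |
| thermodynamics | `gibbs_from_components()`, `gibbs_from_kd()`, `hst5_thermo()`, `check_thermo_consistency()` |
| synthetic data | `synth_saxs_curve()`, `synth_pfg_dataset()`, `debye_form_factor()` |
| I/O and pipeline | `read_saxs_dat()`, `write_saxs_dat()`, `read_pfg_csv()`, `write_xyz()`, `run_config()`, `run_pipeline()` |

Fitted objects have `tidy()`/`glance()` methods and every major result type
has an `autoplot()` method. The methods vignette
(`vignettes/zinc-driven-oligomerisation.Rmd`) documents the model, its
assumptions, parameter choices and limitations.
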