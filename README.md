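# helimsm

Markov state model analysis of SF2-helicase translocation on single-stranded
DNA, built around the XPD / DinG alternating-grip mechanism: during each ATP
hydrolysis cycle the two constrictions of the DNA-binding groove exchange
their hold on the strand — Constriction 2 clamps the 3' end in the apo state
(channel width ~6.1 Å) while the open Constriction 1 (~13.2 Å) lets the 5'
side slide; ATP binding reverses the grip (C1 → 10.7 Å, C2 → 11.7 Å) — and
the enzyme advances by exactly one nucleotide per cycle.

The package is an analysis workflow for resolving that cycle as a sequence of
metastable states and quantifying it:

* **Synthetic data** (`build_xpd_fixture()`, `build_ding_fixture()`,
  `simulate_state_sequence()`, `emit_trajectory()`, `emit_ensemble()`):
  seeded coarse-grained helicase–ssDNA ensembles whose kernels embed the
  reported kinetics exactly (MFPT S1→S2 = 3.6×10⁻³ s, S3→S4 = 4.1×10⁻⁵ s,
  SD1→SD2 = 8.6×10⁻³ s; ~4 ms / ~9 ms cycles), plus per-state constriction
  widths, typed contact patterns and the one-nucleotide register advance.
* **Featurization and TICA** (`build_feature_spec()`, `compute_features()`,
  `fit_tica()`, `tica_project()`, `free_energy_surface()`): Cα / DNA-P
  distance features; the symmetrized lagged-covariance generalized
  eigenproblem C_τ v = λ C₀ v; 2D free-energy surfaces F = −kT ln(p/p_max)
  over (IC1, IC2).
* **MSM** (`kmeans_cluster()`, `count_matrix()`, `estimate_reversible_T()`,
  `implied_timescales()`, `ck_test()`, `pcca_coarse_grain()`,
  `select_n_macrostates()`, `mfpt_and_rates()`, `decompose_pathway()`):
  k-means++ microstates, detailed-balance maximum-likelihood transition
  matrices (x_ij ← (c_ij+c_ji)/(c_i/x_i + c_j/x_j)), implied timescales
  t_i = −τΔt/ln λ_i, Chapman–Kolmogorov validation, PCCA+ fuzzy
  macrostates, first-passage kinetics, and the pathway-versus-trap split.
* **Contacts** (`detect_contacts()`, `persistence_table()`,
  `interface_filter()`, `contact_diff()`, `constriction_contact_counts()`):
  hydrogen bonds (≤3.2 Å, ≥135°), salt bridges (≤3.2 Å), π stacking
  (centroids ≤3.5 Å), hydrophobic contacts (≤4.5 Å); persistent = present
  in ≥75% of a state's frames.
* **Geometry** (`domain_geometry()`, `constriction_width()`,
  `macrostate_centroid()`, `displacement_field()`, `dna_register_offset()`):
  domain centers of mass, the Arch↔Fe–S distance d_A–F and opening angle θ,
  channel widths, Kabsch-superposed Cα displacement fields, and the ssDNA
  register relative to protein landmarks.
* **Mutations** (`build_catalog()`, `classify_mutation()`,
  `mutation_report()`): XP/TTD/CS missense sites classified as
  A (DNA binding / translocation), B (nucleotide binding or RecA1–RecA2
  interface) or C (distal) with supporting contact evidence.
* **Path optimization** (`toy_potential()`, `new_band()`, `neb_force()`,
  `optimize_band()`, `band_delta_rmsd()`): nudged elastic band with
  spring constant 10, simulated annealing, and ΔRMSD < 0.3 convergence,
  exercised on analytic surfaces.

The numbered scripts under `analysis/` run the complete study
(fixtures → landscape → MSM/kinetics → contacts/geometry → mutations →
path optimization) and write their tables under `results/`. The methods
vignette (`vignettes/helicase-translocation-msm.Rmd`) documents the model,
parameter choices and numerical conventions.

## Worked example

```r
library(helimsm)

fx  <- build_xpd_fixture()
res <- run_pipeline(pipeline_config("xpd", seed = 11), fixture_data = fx)

res$n_macro
#> [1] 10
res$template_map                       # macrostate of each ground-truth state
#> S1 S2 S3 S4 S5 S6 S7 T1 T2 T3
#>  3  5  6  7 10  8  9  1  4  2
res$pathway$on_path                    # source -> sink maximum-probability path
#> [1]  3  5  6  7 10  8  9
macrostate_width_table(res)[3, c("template", "c1_mean", "c2_mean")]
#>   template c1_mean c2_mean
#> 3       S1   13.21    6.11

kin <- estimate_fixture_kinetics(fx$fixture, n_frames = 1e7, seed = 7)
kin$mfpt_s("S1", "S2")                 # rate-limiting first step, seconds
#> [1] 0.003705046
kin$mfpt_s("S1", "S7")                 # full cycle: per-nucleotide stepping time
#> [1] 0.004305484
```

The pipeline selects ten macrostates from the implied-timescale spectrum,
seven of which form the translocation pathway in cycle order (the other
three are kinetic traps); frames assigned to the apo macrostate measure a
Constriction 1/2 width of 13.2/6.1 Å, and the estimated kernel reproduces
the embedded passage times within sampling error (3.6×10⁻³ s and ~4 ms
cycle here).

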