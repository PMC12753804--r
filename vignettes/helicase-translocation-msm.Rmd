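---
title: "Markov state modeling of helicase translocation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov state modeling of helicase translocation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

XPD is the 5'→3' single-stranded DNA translocase of the TFIIH complex; its
ATP-driven stepping along ssDNA underlies lesion scanning in nucleotide
excision repair. Structurally it is built from two RecA-like motor domains
(RecA1, RecA2) and two auxiliary domains (Arch and the iron–sulfur, Fe–S,
domain). The DNA groove narrows at two places — Constriction 1 near the 5'
end (walled by RecA2 helices and the P-loop) and Constriction 2 near the 3'
end (between the Fe–S/Arch domains and a RecA1 helical segment). The
mechanistic picture this package analyzes is an alternating-grip cycle: in
the apo enzyme Constriction 2 clamps the DNA (channel width ≈ 6.1 Å) while
the more open Constriction 1 (≈ 13.2 Å) lets the 5' side slide; ATP binding
closes the motor cleft, tightens Constriction 1 (≈ 10.7 Å) and opens
Constriction 2 (≈ 11.7 Å), releasing the 3' end; hydrolysis and ADP release
restore the apo state with the strand advanced by exactly one nucleotide.
The cycle is resolved as a sequence of metastable states — ten for the
XPD-like system (seven on the translocation pathway, S1–S7, plus three
kinetic traps) and nine for the bacterial homolog DinG (five on-path,
SD1–SD5) — with stepwise kinetics quantified as mean first-passage times
(MFPTs): the rate-limiting first step at 3.6×10⁻³ s (XPD) and 8.6×10⁻³ s
(DinG), the ATP-induced opening at 4.1×10⁻⁵ s, and full cycles of ~4 ms and
~9 ms per nucleotide.

The package implements the full analysis chain — distance featurization,
time-lagged independent component analysis (TICA), k-means microstates,
reversible Markov state model (MSM) estimation, PCCA+ coarse-graining,
MFPT kinetics, typed persistent-contact analysis, constriction geometry,
and disease-mutation classification — together with a seeded synthetic
data generator whose ground truth embeds the observables above, so that
every estimator can be validated by parameter recovery without any
external trajectory data.

## The synthetic generator: what it emulates

`build_xpd_fixture()` / `build_ding_fixture()` construct a coarse-grained
topology (~240 pseudo-atoms): per domain a rigid cluster of Cα
pseudo-atoms, one side-chain pseudo-atom for every residue cited in the
contact analyses (e.g. R511, Y627, D234, R112, H135, R196), a
12-nucleotide ssDNA with P, C1' and base-centroid pseudo-atoms, and an
ATP/ADP + Mg²⁺ pseudo-ligand that is parked in bulk solvent in apo states.
Per metastable state a coordinate template realizes the embedded
observables *by construction*:

* **Widths.** Each constriction is walled by two matched rows of
  side-chain pseudo-atoms whose separation equals the embedded width, so
  the package's width metric (symmetrized directed mean of per-residue
  minimum heavy-atom distances) recovers it exactly. Embedded values (Å):

  | state | C1 | C2 |   | state | C1 | C2 |
  |-------|----|----|---|-------|----|----|
  | S1/S7 (apo) | 13.2 | 6.1 | | S4 (ATP) | 10.7 | 11.7 |
  | S2 | 12.6 | 6.4 | | S5 (ADP) | 11.6 | 7.4 |
  | S3 | 11.4 | 8.5 | | S6 | 12.5 | 10.6 |

  Intermediate-state widths are the package's own interpolation; only the
  apo and ATP-bound values are reported quantities. DinG uses a
  systematically wider Constriction 2 (9.0 apo → 14.0 ATP-bound).
* **Contacts.** A curated table of typed contacts (hydrogen bond, salt
  bridge, hydrophobic/stacking) drives the placement of side-chain
  pseudo-atoms: 2.65 Å from the partner for bonds that are "on" in a
  state (3.6 Å for hydrophobic pairs), retracted by 4.5 Å otherwise.
  Detection on noise-free templates therefore reproduces the encoded
  pattern exactly, and the persistent-contact machinery can be tested
  against known ground truth. Stacking interactions are realized as
  hydrophobic contacts because the pseudo-atom topology carries no
  explicit aromatic rings; the π-stack detector is exercised on
  explicit-ring fixtures in the tests.
* **Register.** The DNA threads lattice sites 6.5 Å apart; Constriction 1
  spans sites 2–5, the bridge sites 6–8, Constriction 2 sites 9–12, with
  one overhang nucleotide that alternates between the 5' end (S1) and the
  3' end (S7). The S7 template is the S1 template with the strand advanced
  one site — protein coordinates are bit-identical, which is the defining
  property of a translocation cycle endpoint pair. A 4/3/4 split (rather
  than 4/4/4) keeps both constrictions fully occupied in *both* apo
  registers of the finite 12-mer; the overhang is the price of a finite
  strand.
* **Kinetics.** The transition kernel is a discrete-time birth–death chain
  over the on-path states with one trap attached to each of several
  intermediates. Backward probabilities equal the forward probability of
  the same edge, which makes the on-path stationary mass uniform and the
  chain exactly reversible. Stepwise MFPT targets are imposed in closed
  form: with the recursion u_i = 1 + p_back,i·m_{i-1} + q_i/r_i, the
  forward probability is p_fwd,i = u_i/m_i (m in frames), so the embedded
  MFPTs are exact to machine precision (verified by linear solve in the
  tests). The kernel step is Δt = 10⁻⁶ s, so the fastest embedded step
  (4.1×10⁻⁵ s) spans 41 frames.

**Stepwise MFPTs.** The two quoted steps are pinned (S1→S2 = 3.6×10⁻³ s,
S3→S4 = 4.1×10⁻⁵ s; SD1→SD2 = 8.6×10⁻³ s). The remaining steps are the
generator's own choice: 2.6×10⁻⁴, 1.2×10⁻⁴, 9×10⁻⁵, 9×10⁻⁵ s for XPD
(cycle 4.2×10⁻³ s ≈ 4 ms, dominated by the first step) and 2.0×10⁻⁴,
1.2×10⁻⁴, 8×10⁻⁵ s for DinG (cycle 9.0×10⁻³ s). They are staggered
geometrically rather than set equal, for an identifiability reason: the
macrostate count is selected from the largest implied-timescale ratio, so
the nine (eight) slow relaxation modes must be spaced with no internal gap
ratio approaching the gap between the slowest genuine mode and the
sampling-noise floor of the spectrum (~25–35× at the analysis scale
below). The same reasoning sets the trap exchange rates: traps enter at
q = 3.75–8.25×10⁻⁴ and exit at r = 0.6–2.25×10⁻³ per frame (dwell
0.5–1.7 ms, stationary mass ~0.4 of a pathway state). Much slower traps
would be kinetically "cleaner" but would exchange less than twice per
ensemble at the prescribed sampling, leaving them disconnected from the
count graph and the ten-state decomposition unrecoverable in principle.

* **Emission.** A frame is its state's template plus isotropic Gaussian
  noise, σ = 0.2 Å per coordinate by default — enough to blur atomic
  positions (contact margins are ≥ 2σ√2 away from every cutoff that
  matters) while keeping states separable. `emit_ensemble()` launches
  trajectories round-robin from all states, emulating unbiased runs
  seeded from replicas spread along a transition path.

## What the generator does *not* emulate

No force field, solvent, or thermodynamic realism; no rotational/
translational diffusion of the complex (features are internal distances,
so this is immaterial to the estimators); emission noise is white, so
within-state dynamics decorrelate in one frame — real MD has correlated
fast motions that push implied-timescale noise floors up; domain motions
are pure translations of rigid clusters; the ssDNA register advances as a
rigid lattice shift. Passing the recovery tests therefore demonstrates the
*estimators* are correct and the analysis chain identifies an embedded
Markovian ground truth at realistic noise — it does not certify behavior
on force-field trajectories with non-Markovian memory or poorly separated
states.

## Analysis parameters

Defaults of `pipeline_config()` (the desk-scale "fixture" profile):
60 trajectories × 5000 frames, σ = 0.2 Å; distance features between every
6th Cα plus all DNA P atoms (666 pairs; protein–DNA distances are
included by default because the two apo registers S1/S7 are
indistinguishable from protein coordinates alone — the landscape script
demonstrates this); TICA lag 5 frames, 10 components; k-means k = 200
with k-means++ seeding; MSM lag 1 frame; macrostate count from the
largest implied-timescale ratio among the top 12 (the "full" profile
instead fixes k = 1500, lag 1500 frames, m = 10). These sizes run the full
two-system analysis in ~5 min on one core within ~2 GB; they are the
scale at which all recovery results in the tests are stated.

## Numerical choices

* **TICA.** Mean-free features; C₀ averaged over both ends of each lagged
  pair; C_τ symmetrized, 0.5(C(τ)+C(τ)ᵀ), which keeps eigenvalues real in
  [-1, 1] and makes the fit invariant to time reversal. The generalized
  problem C_τ v = λ C₀ v is solved by whitening with the regularized
  eigendecomposition of C₀ (ε = 10⁻¹⁰·tr(C₀)/d — all-pairs distance
  features are collinear by construction). Components are scaled to unit
  training variance; no kinetic-map weighting.
* **Reversible MSM.** Sliding-window counts; trimming to the largest
  connected component of the *symmetrized* count graph (the
  detailed-balance MLE only requires c_ij + c_ji > 0 on edges); the
  standard fixed-point x_ij ← (c_ij+c_ji)/(c_i/x_i + c_j/x_j), stopped at
  a 10⁻¹⁰ max-entry change.
* **PCCA+.** Inner-simplex algorithm on the top-m right eigenvectors
  (symmetrized in the π inner product): vertices by successive
  farthest-point selection, memberships as clipped/renormalized
  barycentric coordinates, no further rotation optimization — adequate for
  well-separated metastability; the coarse matrix is the π-weighted
  projection χᵀdiag(π)Tχ normalized by χᵀdiag(π)χ.
* **MFPTs** solve the first-passage linear system on the microstate chain
  and aggregate start states by the stationary distribution restricted to
  the source macrostate (the aggregation convention is the package's
  choice). Reported seconds take the frame interval at face value.
* **Pathway split.** On-path = maximum-probability source→sink path on the
  coarse matrix (Dijkstra under edge weight −ln T_ij); everything else is
  a kinetic trap.
* **Contacts.** All cutoffs inclusive (≤ 3.2 Å / ≥ 135° hydrogen bonds,
  ≤ 3.2 Å salt bridges, ≤ 3.5 Å ring-centroid stacking, ≤ 4.5 Å
  hydrophobic). The persistence rule is ≥ 0.75 of a state's frames
  (the threshold is quoted both as "more than" and "at least" 75%;
  the inclusive reading is implemented and tested at the boundary).
  Without explicit hydrogens the donor–H–acceptor angle is evaluated with
  an idealized hydrogen on the donor→acceptor axis (angle 180°, event
  flagged `heavy_atom_only`); the angle comparison carries a 10⁻⁹ degree
  tolerance so that exactly-at-threshold geometries pass. Hydrophobic
  detection is restricted to side-chain nonpolar atoms; events are
  deduplicated to one per residue pair, type and frame.
* **Geometry.** The width metric (directed mean of per-residue minimum
  heavy-atom distances, symmetrized) reduces to the wall separation on
  matched parallel walls and is robust to single displaced atoms.
  Displacement fields use an all-Cα Kabsch superposition. The register
  detector superposes on protein landmarks (the constriction walls) and
  scores candidate offsets by mean nucleotide-position mismatch; ties are
  an error, not a guess.
* **NEB.** Tangents are normalized central differences; the spring force
  k(|Δ_fwd|−|Δ_bwd|) acts along the tangent with k = 10 (the
  energy/length² analog of 10 kcal mol⁻¹ Å⁻²) on a configurable
  coordinate subset (the "partial" scope; all coordinates for the toy
  surfaces). One annealing iteration heats 0→T_max, holds, and cools to 0
  with Gaussian kicks scaled by √T on a damped-dynamics update; iteration
  counts are dimensionless stand-ins for the MD protocol's 2 ns/1 ns/5 ns
  phases, and the mapping from temperature to kick magnitude is a package
  choice (no collision-frequency analog exists for analytic surfaces).
  Convergence is ΔRMSD < 0.3 between annealing iterations over the
  movable replicas, no superposition. A strict consequence of full
  nudging: in 1D the projected potential force vanishes identically, so
  the weak-spring "sliding" sanity property is exercised on a transversely
  confined 2D double well where kinked tangents leak the downhill force.
* **Tie-breaks and seeds.** Lowest index wins everywhere; every stochastic
  step (chain sampling, emission, k-means seeding, annealing kicks,
  centroid subsampling) takes an explicit seed.

## Mutation classification

The packaged catalog (14 XPD missense sites with XP/TTD/CS phenotypes)
is classified by precedence: position in any persistent protein–DNA
contact (any macrostate) → class A; else in the nucleotide-contact set or
the persistent RecA1–RecA2 interface → class B; else class C. The
literature annotation mixes these structural rules with expert judgment,
so the report carries both and flags disagreements: D681, which positions
R683 through a salt bridge without touching DNA itself, is annotated A but
rule-classified C — surfaced, not hidden.

## Known limitations

The estimators assume reasonably well-sampled, reversible dynamics;
irreversible inputs are symmetrized by the MLE rather than rejected. The
macrostate-count selector keys on a single largest spectral gap and will
under-count systems whose slow spectrum contains internal gaps larger than
the gap to the noise floor. PCCA+ without rotation refinement can
misassign microstates when metastability is weak. The synthetic DNA is a
rigid 12-mer lattice; register detection beyond ±3 nucleotides and
fractional-register intermediates are out of scope. The analysis scripts
under `analysis/` are the package's operational interface; there is no
shell-level entry point.
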