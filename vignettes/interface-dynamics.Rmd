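---
title: "Interface dynamics and single-molecule force analysis with ifd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface dynamics and single-molecule force analysis with ifd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifd)
```

`ifd` analyzes how two protein domains bind and how that bond behaves under
force, with the von Willebrand factor (VWF) A1/A2 autoinhibitory complex as
its motivating system. This vignette is the package's account of the models
it implements, the conventions and defaults it chose where the underlying
methods literature leaves room, and what its synthetic-data tests do and do
not demonstrate.

## Interface contacts

A **hydrogen bond** between the domains is scored per frame when the
donor–acceptor heavy-atom distance is below `d_max` (default 3.5 Å,
strict `<`) and an angular criterion below `angle_max` (default 30°) holds
for at least one hydrogen covalently attached to the donor (attachment =
element H within 1.2 Å). Trajectory-analysis tools disagree on where the
angle is measured, so both conventions are implemented:

* `"donor"` (default): the angle at the donor between the D–H bond vector
  and the D→A vector; 0° means the hydrogen points straight at the
  acceptor. This matches the common analysis-tool convention for a
  "< 30°" cutoff.
* `"hydrogen"`: the deviation from linearity at the hydrogen,
  180° − ∠(D–H–A).

For hydrogen-free crystal structures, `require_hydrogen = FALSE` switches
to distance-only detection; requesting hydrogens on a structure without
any raises an error that points at this switch rather than silently
returning nothing.

Donors and acceptors come from a built-in nitrogen/oxygen table (backbone
N/O plus the standard side-chain groups); sulfur is excluded because the
interfaces this package targets are N/O mediated. A **salt bridge** is
scored when any side-chain carboxylate oxygen (ASP OD1/OD2, GLU OE1/OE2)
lies within `d_max` (default 4.0 Å, strict `<`) of a basic side-chain
nitrogen (ARG NE/NH1/NH2, LYS NZ). Histidine is excluded by default —
its protonation state is frame-dependent and the interfaces of interest
contain only D/E × R/K bridges — but `include_his = TRUE` adds ND1/NE2.

Detections are aggregated to **residue pairs** by a union rule: any
qualifying atom-level contact marks the pair present in that frame. This
matches how interface tables are reported (residue pairs, not atom pairs)
and makes the occupancy matrix insensitive to which of, say, two
carboxylate oxygens carries the bond in a given frame.

## Survival rates and run aggregation

The survival rate of a contact is `100 × frames present / total frames`.
Replicate equilibrium runs are aggregated by taking the union of keys; a
pair absent from a run contributes an explicit 0.0% for that run, because
an interface that forms in only one replicate is real but unstable, and
dropping the zeros would overstate it. The summary is mean ± SEM with the
sample (n−1) standard deviation over runs — with three replicates this
reproduces published mean ± SEM interface tables cell-for-cell within
print rounding, which the acceptance tests check for all 18 rows of the
reference tables.

Filtering is by **strict** inequality on the mean (`> 10%` by default,
the conventional cut for heat maps), and sorting is mean-descending with
deterministic tie-breaks (first-run survival, then residue numbers) so
tables are reproducible byte-for-byte. The reference hydrogen-bond table
contains two distinct GLN1367 contacts (with VAL1546 and VAL1548); keys
are residue pairs, so both rows are kept as separate identities.

Bond-count distributions are fitted with a Gaussian
`A·exp(−(x−µ)²/2σ²)` by Levenberg–Marquardt least squares on unit-width
integer bins — counts are integers, so coarser binning would only discard
information. A distribution with all mass in one bin has no sigma support
and raises an error instead of returning a degenerate fit.

## Geometry: superposition, RMSD, surface area

Superposition uses the Kabsch algorithm via SVD with the sign correction
that forbids reflections (rotation determinant +1); collinear point sets
are rejected. Per-frame Cα RMSD superposes each frame's selected CA atoms
onto a reference frame; the value at the reference frame is set to exact 0.

Solvent-accessible surface area is Shrake–Rupley: each atom's sphere is
expanded by the probe radius (default 1.4 Å, water) and sampled with a
**deterministic golden-section spiral** point set (default 960 points).
The deterministic point set was chosen over Monte-Carlo sampling so that
areas are bit-reproducible and buried-area symmetry
(`buried(A,B) = buried(B,A)`) holds exactly; at 960 points the
single-sphere error against the analytic area is far below 1%, and
two-sphere configurations agree with the spherical-cap closed form within
1%. Van der Waals radii come from a built-in Bondi-style element table
(C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80 Å), overridable per call;
unknown elements fall back to 1.70 Å with a warning. Hydrogens are
included in the area when present, and hydrogen-free structures simply
use their heavy atoms — both input styles occur in practice. Which SASA
tool and parameters produced any given published number is usually
unstated; these defaults are declared package choices, not inferences.

PDB ingestion keeps author residue numbering and chain IDs verbatim.
Insertion codes are rejected with an explicit error (analyses key
residues on `(chain, res_seq)`); alternate locations keep the
highest-occupancy conformer, ties broken by file order.

## Docking-pose screening by binding-site occlusion

Published pose screens of this kind are often visual; `ifd`
operationalizes "the blocker occludes the ligand site" as a number. The
ligand's **footprint** on the receptor is every receptor residue with a
heavy atom within `contact_cutoff` (default 4.5 Å) of a ligand heavy
atom. For each candidate pose, the pose receptor is superposed onto the
reference receptor over CA atoms matched by residue number, the transform
is applied to the blocker, and the **covered fraction** is the share of
footprint residues within `contact_cutoff` of the transformed blocker.
Poses below `min_covered` (default 0.5) are excluded; survivors are
ranked by external docking score when supplied (lower = better), else by
coverage, with pose-ID tie-breaks. Both cutoffs are configurable; a
separate `footprint_cutoff` can be frozen while varying the coverage
cutoff, which makes the covered fraction monotone in the latter. The
covered-fraction statistic itself is this package's quantitative
operationalization of a qualitative published criterion.

## Pulling curves: rupture force and dissociation time

The steered-pulling model is a harmonic spring, `F = k(vt − x_steered)`,
with defaults k = 69.48 pN/Å and v = 5 Å/ns (typical constant-velocity
settings for this system). **Dissociation** is defined from contact
annotations, not from the force trace: the earliest sample from which the
interfacial hydrogen-bond count is zero *and* the buried area is below
`sasa_eps` (1 Å²) **through the end of the curve**. The sustained-zero
rule guards against transient zero crossings that a bare
"first time both reach zero" definition would misread as dissociation.
**Rupture force** is the maximum force at or before the dissociation
time, earliest sample on ties. Smoothing (centered moving average,
edge windows shrunk) is off by default — whether published peaks are read
from raw or filtered traces is typically unstated, so both modes are
exposed and the default does not alter data.

## BLI kinetics: global 1:1 Langmuir fit

Association follows `R(t) = R_eq(1 − e^{−k_obs t})` with
`k_obs = k_on·C + k_off` and `R_eq = R_max·C/(C + K_D)`; dissociation is
mono-exponential at `k_off`. The global fit shares one
(k_on, k_off, R_max) across all concentrations — single binding site,
uniform sensor loading — on a log scale (positivity by construction),
with Levenberg–Marquardt minimization from a 3×3 multi-start grid
(k_on ∈ {1e3, 1e4, 1e5} M⁻¹s⁻¹ × k_off ∈ {1e-3, 1e-2, 1e-1} s⁻¹; R_max
started at the maximum observed response). Langmuir fits are
initialization-sensitive, and the grid brackets the micromolar-affinity
regime this package targets; the lowest-RSS start wins, and total failure
reports the start grid in the error. A per-curve R_max option exists but
is off by default. Baselines are assumed pre-subtracted; there is no
drift or mass-transport term. `K_D = k_off/k_on` is computed at full
precision — published K_D values are sometimes rounded independently of
their own printed rates (e.g. 2.16 vs 2.18 µM from the wild-type A1/A2
constants), and the package reports the ratio rather than chasing the
print.

## AFM adhesion statistics

Adhesion frequency is computed per substrate by pooling that substrate's
measurement points (events/cycles × 100); the summary mean ± SEM is taken
**across substrates** with the n−1 rule, matching a design of at least
three independent substrates — per-point variation is visible in the
per-substrate table but does not drive the SEM. Rupture forces of all
adhered cycles are pooled, binned (default 5 pN), and Gaussian-fitted;
the fitted center X_C estimates the most probable rupture force and is
less outlier-sensitive than the arithmetic mean, which is reported
alongside. At least 20 events are required before a distribution fit is
attempted.

## Synthetic data: what it does and does not emulate

Every generator is seed-deterministic (byte-identical outputs, local RNG
that leaves the caller's stream untouched) and returns a ground-truth
manifest; recovery tests compare against the manifest, never against
re-derived numbers.

* `make_toy_complex` / `make_trajectory` plant donor/H/acceptor triples
  and carboxylate/ammonium pairs at requested geometries and toggle them
  per frame (Bernoulli or two-state Markov started from its stationary
  distribution) by displacing the partner atom 6 Å along the pair axis —
  beyond every cutoff. Occupancy patterns are statistical stand-ins: no
  force field, no correlated side-chain motion, no partial-geometry
  near-misses beyond what the planted distances/angles encode.
* `make_smd_curve` produces a ramp that reaches its exact planted peak at
  the planted rupture time (a near-flat 2%-tilted shoulder precedes the
  peak, keeping the argmax unique but making the peak robust to
  smoothing), collapses afterwards, and decays its contact annotations to
  zero exactly at the planted dissociation time. Real pulling traces show
  multiple partial unbinding events; this generator plants exactly one.
* `make_sensorgram_set` and `make_afm_cycles` draw additive Gaussian noise
  and Bernoulli adhesion at the standard designs (six concentrations
  125–4000 nM, 60 s/120 s phases; 3 substrates × 5 points × 100 cycles).
  Heavier-tailed noise, baseline drift, and nonspecific-adhesion
  mixtures are deliberately not modeled.

Passing recovery tests therefore demonstrates that the *analysis* chain is
correct and unbiased under its own model assumptions — it does not
validate those assumptions against instrument data, and trajectory-scale
published quantities (rupture forces of hundreds of pN, dissociation
times of tens of ns) enter only as generator presets, not as recomputable
results.

## Problem sizes and numerical tolerances

The test suite and acceptance script size their simulations for
desk-scale reproducibility: 5,000–10,000 frames for binomial occupancy
recovery (3σ bounds), 20 seeded replicates for noisy Langmuir fits
(median K_D error < 5% at 2% response noise), 50 seeded pulling curves at
σ = 20 pN (per-curve error within 4σ/√window, mean within 2σ/√window —
the peak of a smoothed noisy ramp is an extreme-value statistic with
positive bias, hence the wider per-curve envelope), 100 random geometries
for exhaustive-oracle equivalence of the contact detectors, and 960-point
SASA against 1% analytic tolerances. Noiseless recovery asserts exactness
(Langmuir rates to 0.1%, rupture/dissociation to machine precision).

## Known limitations

* Trajectories are multi-model PDB only; no DCD/XTC readers.
* No π-stacking, cation–π, or hydrophobic-contact detection; no
  force-field energies.
* The Langmuir module fits a single-site model only — no mass-transport
  limitation, bivalent analytes, or regeneration carry-over.
* No worm-like-chain or loading-rate (Bell–Evans) analysis of rupture
  forces; AFM input is assumed already calibrated to forces.
* SASA is O(n²) in atoms per frame with plain neighbor pruning; it is
  meant for interface-sized selections, not proteome-scale batches.
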