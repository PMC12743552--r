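# ifd — protein interface dynamics and single-molecule force analysis

`ifd` is an R toolkit for quantifying how two protein domains hold on to each
other, built around the autoinhibitory complex between the A1 and A2 domains
of von Willebrand factor (VWF). In circulating VWF the A2 domain shields the
GPIbα-binding site on A1; characterizing which interfacial residues maintain
that grip — and how strong it is mechanically and kinetically — requires the
same analysis chain whether the raw data come from molecular-dynamics
trajectories, biolayer interferometry (BLI), or AFM force spectroscopy. The
package implements that chain end to end:

- **Docking-pose screening** — given a reference receptor/ligand complex
  (e.g. A1/GPIbα), score candidate receptor/blocker poses by how completely
  the blocker occludes the ligand's binding footprint (covered fraction of
  footprint residues within a 4.5 Å contact cutoff after Cα superposition).
- **Interface contacts** — per-frame detection of interdomain hydrogen bonds
  (donor–acceptor distance < 3.5 Å and angular deviation < 30°, donor- or
  hydrogen-centered convention) and salt bridges (acidic-O to basic-N
  distance < 4 Å).
- **Occupancy statistics** — bond survival rates (percent of frames a
  contact persists), aggregation over replicate runs as mean ± SEM (n−1
  rule), strict-threshold filtering, residue-pair heat-map matrices, and
  Gaussian fits of bond-count distributions.
- **Core geometry** — Kabsch superposition (SVD with reflection guard),
  per-frame Cα RMSD, Shrake–Rupley solvent-accessible surface area on a
  deterministic golden-spiral point set, and buried interface area
  SASA(A) + SASA(B) − SASA(AB).
- **Force spectroscopy** — rupture force (peak of the force–time curve
  before dissociation, with the dissociation time defined by sustained loss
  of hydrogen bonds and buried area), the harmonic spring-pulling model
  F = k(vt − x), AFM adhesion frequency per substrate, and Gaussian-fitted
  rupture-force distributions (most probable force, X_C).
- **Binding kinetics** — 1:1 Langmuir sensorgram simulation and global
  nonlinear fitting of serial-dilution BLI data sharing (k_on, k_off, R_max)
  across concentrations, with K_D = k_off / k_on.
- **Synthetic data** — seed-deterministic generators for every input class
  (trajectories with planted per-frame bond occupancies, pulling curves with
  planted rupture, sensorgram sets, AFM contact cycles), each returning a
  ground-truth manifest so recovery can be tested without any external data.

Structure I/O is multi-model PDB (via bio3d), with author residue numbering
kept verbatim; tabular formats are plain CSV/JSON with unit-suffixed columns.

## Worked example

```r
library(ifd)

# 1. Aggregate per-run bond survival (three replicate equilibrium runs)
tab  <- vwf_survival_runs("hbond")
runs <- lapply(c("run1", "run2", "run3"),
               function(cl) setNames(tab[[cl]], tab$pair))
agg  <- aggregate_runs(runs, kind = "hbond")
head(filter_table(agg, 50), 3)
#>    kind        pair res_a res_b run1 run2 run3     mean       sem
#> 1 hbond R1334-E1598  1334  1598 79.3 59.1 51.1 63.16667  8.390736
#> 2 hbond Q1367-V1546  1367  1546 78.1 74.8 27.9 60.26667 16.211347
#> 3 hbond D1323-R1575  1323  1575 67.7  5.7 88.7 54.03333 24.915412
```

Only three hydrogen bonds survive in more than half of all frames —
R1334–E1598, Q1367–V1546 and D1323–R1575 — marking them as the load-bearing
contacts of the interface (printed as mean ± SEM over runs, e.g. 63.2 ± 8.4%).

```r
# 2. Global 1:1 Langmuir fit of a noisy six-concentration sensorgram set
gen <- make_sensorgram_set(kon = 1.7e4, koff = 3.7e-2, Rmax = 0.5,
                           noise_sd = 0.01, seed = 42)
fit_langmuir_global(gen$curves)
#> langmuir_fit: kon = 1.68e+04 /M/s, koff = 0.037 /s, KD = 2.2e-06 M (2.20 uM), rss = 0.222

# 3. Rupture analysis of a noisy synthetic pulling curve
smd <- make_smd_curve(rupture_force_pN = 358.7, rupture_time_ns = 20,
                      dissociation_time_ns = 21.6, noise_sd = 20, seed = 42)
rupture_force(smd$curve, smooth_window = 11)
#> pulling_result: rupture 372.9 pN at 19.80 ns; dissociation at 21.60 ns

# 4. AFM adhesion statistics (3 substrates x 5 points x 100 cycles)
afm <- make_afm_cycles(p_adhesion = 0.191, force_mean = 42.2, force_sd = 8,
                       seed = 42)
adhesion_frequency(afm$cycles)
#> adhesion_summary: 21.2% +/- 0.7% (SEM, n = 3 substrates)
rupture_distribution(afm$cycles)
#> rupture_distribution: Xc = 42.3 pN, mean = 41.7 pN (n = 318 events)
```

The fitted K_D (2.20 µM here) recovers the generating k_off/k_on = 2.18 µM
within the noise; the rupture peak and the contact-defined dissociation time
come back within the expected smoothed-noise envelope of their planted
values; and the adhesion frequency estimate sits within binomial sampling
error of the planted 19.1% event probability.

## Vignette

`vignettes/interface-dynamics.Rmd` documents the models and conventions in
detail: contact criteria and angle conventions, the survival/SEM rules,
SASA numerics, the Langmuir parameterization and multi-start strategy, what
the synthetic generators do and do not emulate, and known limitations.
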