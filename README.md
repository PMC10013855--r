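# ternarymd

Trajectory analysis for agonist–GPCR–G protein ternary complexes.

When a G protein-coupled receptor (GPCR) such as the beta-2 adrenergic
receptor binds its agonist and couples to the stimulatory G protein (Gs),
the G-alpha subunit's helical domain can swing open relative to its
Ras-like domain, and the complex can begin to dissociate. Molecular
dynamics studies of this process lean on a standard analysis chain, which
this package implements as tested, reusable R functions:

* **Collective variables** — geometric-center distances, interdomain
  orientation angles, least-squares-fit RMSD series, trailing-window
  averages (`center_distance_series`, `interdomain_angle_series`,
  `rmsd_series`, `window_average`).
* **State classification** — the G-alpha opening coordinate (A161–E299
  center distance) mapped to closed / semi-closed / semi-open / open with
  thresholds 35 / 45 / 55 Å (`classify_series`, `occupancy`,
  `transition_counts`).
* **Contacts** — persistent-contact fingerprints: a residue is in the
  binding pocket or interface when within 3 Å for more than half of the
  frames (`persistent_contacts`, `interface_residue_count`,
  `mean_interaction_time`).
* **Pose clustering** — pairwise ligand RMSD in the receptor frame, Ward
  linkage, elbow selection of the cluster count, populations and medoid
  representatives (`cluster_poses`).
* **Free energy** — 1D/2D potentials of mean force, W = −kB·T·ln p, with
  0.5 Å / 5° bins and a 10-count 2D cutoff, second-order
  cumulant-expansion reweighting of Gaussian-accelerated (GaMD) boosted
  ensembles, and exact grid-graph barrier extraction (`pmf_unbiased`,
  `pmf_reweighted`, `pmf_2d`, `minima_and_barrier`).
* **Energetics** — MM–PBSA assembly ΔG = ΔH + (−TΔS) from per-frame
  component tables, interaction entropy
  −TΔS = kB·T·ln⟨exp(β·ΔE_int)⟩, block-average SEM, and energy-bin
  reweighting for boosted runs (`assemble_dG`, `interaction_entropy`,
  `block_sem`, `reweight_energy`).
* **Correlation** — Pearson r with degeneracy checks, per-run
  window-average scatter, and time-lagged cross-correlation r(τ) for τ up
  to half the trajectory (`pearson`, `window_scatter`, `lag_correlation`).
* **Synthetic data** — seed-deterministic generators for every stage:
  overdamped Langevin dynamics on a calibrated double well (minima 34 and
  62 Å, adjustable barrier and asymmetry), GaMD-style boosts with recorded
  per-frame ΔV, correlated/lagged CV pairs, and toy receptor–ligand
  complexes with planted pose clusters and scripted contacts
  (`make_opening_double_well`, `simulate_langevin`, `gamd_boost`,
  `correlated_cv_pair`, `make_toy_complex`).

Structures are read from PDB and trajectories from DCD (via bio3d);
residue groups are defined by chain + author-numbered residue ranges,
directly or from a YAML config.

## Worked example

Simulate the opening coordinate on the calibrated double well, classify
states, and recover the free-energy profile:

```r
library(ternarymd)

pot <- make_opening_double_well(closed_pos = 34, open_pos = 62,
                                barrier = 2.5, asymmetry = 1)
cv  <- simulate_langevin(pot, n_steps = 1e6, dt = 0.01, x0 = 62, seed = 42)

occupancy(classify_series(cv))
#>      closed semi_closed   semi_open        open
#>    0.083591    0.074749    0.045480    0.796180

pm <- pmf_unbiased(cv, bin_width = 0.5, count_cutoff = 100)
mb <- minima_and_barrier(pm)
round(mb$barrier, 2)
#> [1] 2.56
```

The run spends ~80% of its time open — the open basin is 1 kcal/mol lower
and entropically wider — and the estimated barrier between the closed
(34 Å) and open (62 Å) basins reproduces the generating 2.5 kcal/mol to
within sampling error. Assembling a published-style free-energy
decomposition is exact arithmetic:

```r
assemble_dG(-21.61, 6.88)
#> dH = -21.61  -TdS = 6.88  dG = -14.73 kcal/mol
```

The numbered drivers under `analysis/` run the full workflow on synthetic
data (opening simulation → PMF recovery → pose/contact analysis →
energetics → correlations) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_opening.R
Rscript analysis/02_pmf_recovery.R
# ... through 05
```

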