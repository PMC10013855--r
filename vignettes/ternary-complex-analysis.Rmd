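---
title: "Analysing agonist-GPCR-G protein dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing agonist-GPCR-G protein dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ternarymd)
```

## The scientific problem

When an agonist-bound G protein-coupled receptor (GPCR) such as the beta-2
adrenergic receptor engages its stimulatory G protein (Gs), the G-alpha
subunit's helical domain (GsaAH) can swing away from its Ras-like GTPase
domain (GsaRas) -- the "opening" that accompanies nucleotide exchange -- and
the complex eventually dissociates. Multi-microsecond molecular dynamics
trajectories of such ternary complexes are interrogated with a recurring
set of measurements: geometric-center distances and interdomain angles as
collective variables (CVs), threshold-based conformational-state
assignment, persistent-contact fingerprints of binding pockets and
protein-protein interfaces, hierarchical clustering of ligand binding
poses, potentials of mean force (PMFs) over one or two CVs, end-point
MM-PBSA binding free energies with an interaction-entropy term, and
time-lagged correlations that ask which domain motion leads which.
`ternarymd` implements that analysis chain as reusable, tested functions,
together with a synthetic-trajectory module that generates data with the
exact statistical structure each estimator assumes, so the whole chain is
verifiable without multi-terabyte raw trajectories.

## Collective variables

All distances and angles are measured between *geometric centers*:
unweighted arithmetic means of atom coordinates, with no mass weighting.
Groups default to heavy atoms -- published figures omit hydrogens, and
heavy-atom centers are insensitive to hydrogen placement, which differs
across force fields; `atom_subset_rule` (`heavy`, `calpha`, `all`) is
exposed rather than guessed because source analyses rarely state it.
The interdomain orientation angle uses two vectors, each from a domain's
center to an anchor residue's center (for G-alpha: the AH-domain center to
A161, and the Ras-domain center to E299), reported in [0 deg, 180 deg].
RMSD series are least-squares-fit RMSDs (Kabsch superposition) computed on
the same atom selection used for fitting; the `average_structure` reference
first superposes all frames on frame 1, averages, then fits each frame to
that mean structure. The variance-minimizing property of the mean makes
this reference give the smallest achievable mean RMSD, which the test suite
checks empirically.

Residue selection uses PDB author numbering plus chain throughout,
including in YAML group configs; receptor selections "without intracellular
loops" are expressed as explicit kept ranges in the config, never
hard-coded. Internally everything is 1-based, the natural R convention.

## State classification of G-alpha opening

The opening coordinate is the A161-E299 center distance. Four states are
assigned by thresholds (defaults 55, 45, 35 Angstrom): fully open at
>= 55, semi-open in [45, 55), semi-closed in (35, 45), closed at <= 35.
The boundary convention preserves the inclusive inequalities at the outer
bounds (>= 55 open, <= 35 closed) and assigns 45.0 to semi-open; the
interior boundaries are half-open so every distance maps to exactly one
state and classification is monotone in distance. Raw thresholding is used
deliberately -- no hidden-Markov smoothing -- matching how such states are
reported. A known limitation inherited from the distance CV itself: a
"flipped-up" AH domain can sit geometrically close to the Ras domain while
the fold is effectively closed, so a mid-range distance does not always
mean a partially open structure; the interdomain angle CV exists to flag
such cases, and no corrected classifier is attempted.

## Contacts and persistence

A target residue is in contact with a probe group in a frame when the
minimum heavy-atom pair distance is within the cutoff (default 3.0
Angstrom, boundary inclusive -- "within"). The persistent set is residues
in contact in *strictly more than* a persistence fraction of frames
(default 0.5, i.e. more than half), so 6 of 10 frames qualifies and 5 of
10 does not. Mean percentage interaction time is 100 times the mean
contact fraction over a residue subset (default: the persistent set).
Residues belonging to the probe are never reported as targets
(self-contact exclusion), and no periodic-boundary minimum-image handling
is applied by default since analyses of a whole, wrapped complex do not
need it. Hydrogen-bond angular criteria are out of scope: only distance
contacts are computed.

## Ligand pose clustering

Frames are superposed on a receptor fit group (reference: frame 1), then
the ligand RMSD between every pair of frames is computed *without further
fitting*, so poses are compared in the receptor frame; the matrix is a
metric on rigid-pose fixtures. Ward's minimum-variance linkage
(`hclust(method = "ward.D2")` on the RMSD values, the same algorithm the
field's clustering tools call) provides a partition for every k, and the
cluster count is selected by an elbow criterion on within-cluster sum of
squares (WSS), computed from pairwise distances as
sum over clusters of sum of squared within-cluster distances divided by
cluster size.

The elbow is the point of maximum distance below the chord joining the
first and last points of the *log* WSS-versus-k curve. The log scale is a
deliberate design choice: WSS spans orders of magnitude across k, and on
the raw scale the chord criterion is dominated by the first, most
expensive merges -- on planted equal-population blobs it reliably selects
k-1. On the log scale the pre-knee decay is near-linear and the knee is
the unique extreme point; a profile with no point more than a factor of 2
below its chord (the signature of a single structureless blob, whose
log-WSS is smoothly concave) returns k = 1. The criterion is
deterministic: no RNG is involved anywhere in clustering. Populations are
percentages of frames; each cluster's representative is its medoid, the
frame with the smallest mean RMSD to the other members, ties broken by
lowest frame index. Populations are computed over all supplied frames;
restricting to a window is the caller's decision.

## Potentials of mean force

The unbiased estimator is the histogram PMF
W(bin) = -kB T ln(n_bin / n_max), shifted so the minimum over unmasked
bins is exactly 0 (only relative free energies are meaningful). Default
bin widths are 0.5 Angstrom for distances and 5 degrees for angles; 2D
grids mask bins with fewer than 10 configurations by default (1D default
is 1). The grid spans whole bin widths from floor(min) to ceil(max), edge
bins included. Temperature defaults to 310 K, the physiological simulation
condition, with kB = 0.0019872041 kcal/mol/K.

Boosted (Gaussian-accelerated MD) ensembles are reweighted per bin by the
second-order cumulant expansion of ln of the exponential boost average:
ln p = ln p* + beta c1 + beta^2 c2 / 2, with c1 and c2 the per-bin mean
and variance of the boost Delta-V. Order 2 is the default and order 1 is
available; higher orders are rejected because their estimates are
dominated by noise. Two exact identities anchor the implementation: a zero
boost and a constant boost both reproduce the unbiased PMF *bit for bit*
(a constant shifts every bin equally and cancels in normalization), and
the test suite asserts `identical()`, not approximate equality. Bins where
the variance cannot be estimated (fewer than 2 boosted samples) are
masked rather than silently zeroed.

Barriers between minima are computed exactly on the grid graph
(4-connectivity in 2D) as bottleneck path values: the smallest threshold t
at which the two minima are connected through bins with W <= t, found by
binary search over the sorted bin values with breadth-first connectivity;
the tests compare against exhaustive path enumeration on small grids.
No multi-ensemble estimator (WHAM/MBAR) is provided: single-ensemble
reweighting is the method re-implemented here.

## MM-PBSA assembly and interaction entropy

Per-frame energy components (gas-phase electrostatics, van der Waals,
polar and nonpolar solvation) are *consumed* from CSV -- the
Poisson-Boltzmann solver, implicit membrane and surface-area models are
out of scope -- and the enthalpy is their mean over a time window. The
entropic term is the interaction entropy,
-T dS = kB T ln < exp(beta dE) >, with dE the fluctuation of the
gas-phase interaction energy about its mean, evaluated with log-sum-exp
stabilization. It is non-negative by Jensen's inequality, exactly zero
for constant input, equals kB T ln cosh(beta eps) for symmetric two-point
fluctuations and approaches beta sigma^2 / 2 for small Gaussian
fluctuations -- all three closed forms are asserted in the tests.
dG = dH + (-T dS) holds exactly by construction. Uncertainty is the
block-average SEM over 5 contiguous blocks by default: no block count is
standard, and 5 blocks over a 2-microsecond analysis window gives 400 ns
blocks, long relative to the CV autocorrelation visible in such
trajectories.

For boosted runs only the energy term is reweighted, via the energy
histogram (0.5 kcal/mol bins), per-bin cumulant PMF W, bin probabilities
exp(-beta W), and the probability-weighted mean of biased bin means.
Entropy reweighting is deliberately not implemented: the higher-order
cumulant terms dominate and the estimate diverges. A toy gas-phase
Coulomb + 12-6 Lennard-Jones evaluator (Coulomb constant 332.0636
kcal mol^-1 Angstrom e^-2, Lorentz-Berthelot combination, no cutoffs)
exists solely to make end-to-end tests self-contained; it is not a stand-in
for a solvation model and is documented as such.

## Correlations

Pearson r is computed by `stats::cor` behind a surface that rejects
degenerate input (fewer than 3 samples, zero variance) instead of
propagating NaN. Time-lagged correlation compares x(t) with y(t + tau)
for tau from 0 to at most half the series duration -- beyond half, the
overlap is too short to be meaningful -- using only the overlapping
samples (no padding); positive lag means y is observed later, and
negative lags are not computed. Per-run summaries average each CV over
the final window (default 2000 ns) and correlate the per-run means across
runs; with fewer than 3 runs the means are reported and r is omitted. No
significance testing is attached, matching the descriptive use of these
coefficients.

## The synthetic-data module

The generators define the study conditions for every test:

* **Opening double well.** A quartic potential whose gradient is
  c (x - a)(x - s)(x - b), with minima pinned *exactly* at the closed
  (34 Angstrom) and open (62 Angstrom) positions; the saddle position s
  and scale c are solved (one-dimensional root find) so the barrier above
  the lower minimum and the well-depth difference are met exactly, which
  requires barrier > |asymmetry|. Defaults: barrier 2.5 kcal/mol (the
  observed small barrier is 2-3 kcal/mol) and asymmetry 1 kcal/mol with
  the open well lower, since the open state is the energetically favored
  one.
* **Dynamics.** Overdamped (Brownian) Euler-Maruyama integration with
  diffusion D (default 50 Angstrom^2/ns) at 310 K: only equilibrium
  distributions and correlation structure matter for testing estimators,
  not inertial kinetics. The stationary density is Boltzmann, verified by
  chi-squared against the analytic density on thinned samples. Timesteps
  violating dt <= 2 / (beta D kmax) are rejected with the admissible
  maximum reported; the default dt of 0.01 ns sits ~15x below the limit
  for the default well, and tests that probe exact variances use smaller
  steps so the discretization bias stays well under sampling error.
* **GaMD-style boost.** Delta-V = k/2 (E - V)^2 below the reference
  energy E, zero above; E follows the lower-bound convention (E = Vmax
  over the domain) and k = k0/(E - Vmin), k0 in (0, 1]. The boost is zero
  wherever V >= E by construction, boosted runs record per-frame Delta-V,
  and with the default well the realized boost SD (~0.4 kcal/mol) sits
  far below the 6.0 kcal/mol cap used in production GaMD runs.
* **Correlated CV pairs.** Exact-rho Gaussian mixing for iid pairs;
  Ornstein-Uhlenbeck pairs (correlation time 10 ns by default) where y
  mixes the lag-shifted x with an independent OU innovation, giving a
  cross-correlation peak of height rho at the planted lag.
* **Toy complexes.** Receptor residues (3 heavy atoms each) on a 14
  Angstrom ring; the ligand visits k pockets on an inner circle with
  0.25 Angstrom jitter, far below the >= 4-6 Angstrom pocket separation.
  Pocket angles and radii are mildly irregular (a deterministic +/-12%/6%
  perturbation of the regular polygon): exactly regular polygons make
  Ward merge costs degenerate in k and the elbow ill-posed, while strong
  irregularity would create pocket super-groups. Scripted contacts dock
  chosen residues at 2.5 Angstrom from the ligand center along distinct
  cone directions for a prescribed fraction of frames; construction
  self-validates -- the emitted ground-truth table is re-derived from the
  generated geometry and any infeasible script (collisions, unreachable
  contacts) is an error, so a fixture can never disagree with its own
  truth.

Every generator is seed-deterministic and emits its ground truth
(potential parameters, pose schedule, contact table) for parameter-recovery
tests.

What the generators do *not* emulate -- and therefore what passing tests do
not show about real data: all-atom structure (no side chains, no membrane,
no solvent), periodic boundaries, force-field energetics beyond the toy
evaluator, state-dependent kinetics beyond a 1D diffusion, and the
"flipped-up" AH-domain geometry that can fool the distance-based state
classifier. The chain is validated as *estimators applied to data with
known answers*, not as a re-simulation of the biology.

## Problem sizes and numerical choices

The default test and acceptance workloads use 10^6-step Langevin runs
(dt 0.01 ns, i.e. 10 microseconds of CV dynamics) for PMF recovery --
enough for ~100+ barrier crossings of the 2.5 kcal/mol barrier at 310 K --
10^5-sample correlation recoveries, and 100-frame toy complexes. At these
sizes the unbiased PMF reproduces the generating potential to < 0.1
kcal/mol RMSE over bins with >= 100 counts (acceptance bound 0.3), and the
cumulant-reweighted boosted PMF to < 0.1 (bound 0.5). PMF comparisons
align estimate and truth by their mean offset, since a PMF is defined only
up to a constant. Degenerate inputs are errors, not warnings: empty
selections, zero-variance correlations, all-masked grids, non-positive
distances for state assignment, overlapping atoms in the toy evaluator.

## Structure-pathway check without deposited coordinates

The A161-E299 opening distance of an open-state complex (~62 Angstrom in
the crystallographic starting structure of such simulations) is exercised
through a *synthetic* open-state G-alpha CA-trace model
(`make_synthetic_gsa_open()`): two confined CA random-walk domains with
author-numbered residues, positioned so the anchor separation equals the
open-state value. It validates the full pipeline -- PDB write and re-read,
group resolution by author numbering, center distance, state assignment --
but because its geometry is fixed by construction it is a pipeline check,
not an independent measurement of the experimental structure; it is
labelled synthetic everywhere it appears.

## Known limitations

* Trajectory input is CHARMM/NAMD-style DCD (plus PDB structures); XTC is
  not read -- no reader exists in this package's dependency set and the
  compressed XTC codec is out of proportion to its value here.
* The distance-based state classifier cannot distinguish a flipped-up AH
  domain from genuine closing (see above).
* No helicity metric is provided for partial helix unwinding; that
  observation remains qualitative.
* Single-ensemble reweighting only; no WHAM/MBAR, no normal-mode or
  reweighted entropies, no screened-electrostatics MM-PBSA variant.
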