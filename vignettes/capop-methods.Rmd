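---
title: "Methods: population analyses for two-context calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population analyses for two-context calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capop)
```

This vignette is the package's account of its own methods: the statistics it
computes, the assumptions behind them, the synthetic data they are validated
against, and the numerical and design choices made where the procedures left
room. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The experimental structure being analyzed

The pipeline targets longitudinal one-photon calcium imaging of hippocampal
populations during repeated training in two discriminable contexts (trials
alternate between contexts within each daily session), followed by an
unreinforced probe session whose trials carry a treatment label (vehicle,
VEH, or the DREADD agonist C21) — the setting for asking whether
artificially reactivating a tagged engram reinstates a context-specific
population state. Inputs are assumed to be post-processed: denoised
fluorescence traces and non-negative deconvolved transients at 5 Hz (so one
bin is 200 ms), a trial table, head-position/digging/sniffing behavior
streams, and cross-session cell-registration maps. None of the upstream
algorithms (source extraction, deconvolution, registration, pose tracking)
are reimplemented here; their outputs are the bundle format's contract.

## Behavioral exclusion masks

All context statistics are computed on *kept* bins. A bin is excluded when
the head is inside a 40 x 40 pixel axis-aligned box centered on either
reward well (boundary inclusive — the anchoring and boundary rule are the
package's choice, as box size is the only stated quantity), when the
digging or sniffing stream is true (probe analyses only), or when no trial
covers it. Training analyses use `{reward_zone, outside_trial}`; probe
analyses add `{digging, sniffing}`. These defaults are wired into the CLI
pipeline and asserted in tests. Masking is monotone: adding an exclusion
can only shrink the kept set.

## Population-vector distance ratio

For each trial, the PV is the per-cell mean of the denoised trace over the
trial's kept bins. With cosine distance $d(a_i,a_j) = 1 - \cos(a_i,a_j)$,
the separation statistic is the ratio of the mean over ordered
different-context pairs to the mean over ordered same-context pairs. Its
chance level repeats the computation over 10 random permutations of the
trial labels and averages. The implementation follows the closed-form
ratio; an independent $O(n^2)$ ordered-pair loop serves as the oracle in
tests (agreement to 1e-10 on random instances).

Assumptions worth knowing: the ratio needs at least two PVs per context and
a nonzero within-context distance sum; trials whose kept set is empty are
dropped; contexts must be exactly two.

## Latent-space distribution distance

Per training day, PCA is fitted to the day's kept 200-ms PVs, bins are
projected on the first $N = 5$ components ($N \le 3$ in tests and the CLI
default — see *Problem sizes*), and scores are z-scored per dimension. Each
context's distribution in this latent space is estimated by a Gaussian
product-kernel KDE with a shared isotropic bandwidth $h$, and the two
densities are compared by the symmetric Kullback–Leibler divergence summed
over a regular grid spanning $[-10, 10]$ per dimension with spacing $h$.

Numerical choices:

- **Kernel grid for cross-validation.** 15 log-spaced candidates in
  $[0.05, 2]$ z-units. The optimum is selected per day by 4-fold CV
  held-out log-likelihood on a random 10% subsample of bins, and the final
  kernel is the mean of the per-day optima. On unit-variance latent data
  the selected kernel sits in the grid's interior (asserted in tests).
- **Grid normalization and flooring.** Densities are normalized to sum to
  one over the grid, then floored at $\varepsilon = 10^{-12}$ before the
  logarithms; without a floor the divergence is undefined whenever a grid
  cell is empty on one side. The divergence is 0 iff the two normalized
  grid densities coincide.
- **Grid pruning.** Grid points farther than 12 kernel widths from every
  sample on both sides have normalized density far below the floor, so
  both sides floor to $\varepsilon$ there and the pruned points contribute
  exactly zero to the sums; they are skipped. This is a speed
  optimization, not an approximation at double precision.
- **Monte-Carlo cross-check.** `latent_kl_mc()` estimates the same
  divergence by sampling from the two kernel densities; tests require
  agreement with the grid computation.
- **Label permutations at trial granularity.** The chance level permutes
  context identity over trials, not bins, preserving within-trial
  autocorrelation, which matches the trial-labeled design.

## Spectral embedding and trial warping

Trajectory visualization reduces 1-s PVs to two dimensions with a Laplacian
eigenmap: an unweighted k-NN graph ($k = \lfloor m/10 \rfloor$, neighbor
relation symmetrized by union), the unnormalized Laplacian $L = D - A$, and
the eigenvectors of the two smallest nonzero eigenvalues. A disconnected
graph is an error advising a larger $k$ rather than a silent per-component
embedding, because eigenvector selection is ill-defined across components.
Variable-length trials are compared by linear interpolation to 1000 evenly
spaced samples with endpoints preserved.

## Cross-session similarity

The average-activity PV integrates the denoised trace over kept bins.
Similarity between two sessions restricts both vectors to registered shared
cells, z-scores each across cells, and multiplies: $c_i = z_{i,1} z_{i,2}$.
The z-scoring uses the **population SD convention** (divide by $n$), chosen
so that self-similarity is exactly 1 — a clean calibration point asserted
in the tests. Whether to z-score across cells or across time was open; the
formula's symbols (session mean and SD over *cells*) decide it: across
cells.

The NCM normalizes each cell pair's Pearson correlation against a null of
100 circular rotations (offsets uniform on $[1, bins-1]$, drawn
independently per cell per shuffle, masked bins removed before rotation).
Rotation preserves each trace's autocorrelation while destroying
cross-trace alignment, which is the point: the normalized value isolates
temporal coupling from average-rate and transient-shape differences. On
independent cells the normalized values are calibrated (grand mean near 0,
SD near 1; asserted). Cross-session NCM similarity correlates, per shared
cell, its normalized-correlation profile over shared partners in the two
sessions; cells with fewer than two valid partners are omitted and counted.

## Ensemble extraction and activation

Ensembles are eigenvectors of the correlation matrix of the kept population
activity whose eigenvalue exceeds the circular-shuffle null mean by more
than one null SD. The null summary is the **largest eigenvalue of each
shuffled correlation matrix** (100 shuffles). This is a deliberate design
choice: pooling entire shuffled spectra cannot calibrate the 1-SD rule,
since any spectrum — including pure noise — places roughly 15% of its mass
above its own mean + 1 SD, which would flag a dozen "ensembles" in
structureless data; the largest shuffled eigenvalue instead tracks the
spectral edge that genuine coactivity must exceed, and white-noise sessions
then yield at most a couple of significant ensembles (asserted over seeds).
Eigenvector signs are fixed by making the largest-magnitude loading
positive, so downstream dot products are reproducible. Constant cells are
excluded with a warning.

Activation scoring downsamples the target session to 1-s bins (a bin is
kept only if all five constituent samples are kept), z-scores each cell
across the session, restricts the loading vector to registered shared
cells (re-normalized to unit norm), and normalizes the dot product per bin
against 1000 cell-identity shuffles of the loadings; $z > 2$ marks
significant activation. Per-cell z-scoring of the activity vector is the
package's resolution of an open point: it stops high-rate cells from
dominating the dot product and makes the cell-ID-shuffle null meaningful.
A uniform loading vector is degenerate by construction (every shuffle is
identical; bins are marked undefined). Probe activation rates count
significant bins per trial and ensemble group (tagged- vs
non-tagged-context extraction) normalized by the session's total, so the
two groups' fractions sum to one.

## Synchronous calcium events

The fraction of active cells (binarized transients, threshold at zero) per
bin is smoothed with a Gaussian kernel of sigma 50 ms, z-scored over the
session, and thresholded one-sided at $z > 2$. At the 5 Hz analysis rate
50 ms is 0.25 bins, making the smoothing effectively the identity; the
function is implemented literally and accepts the 20 Hz stream (smooth
first, then `downsample()`) for the other reading of the order of
operations. Gaussian kernels are truncated at 4 sigma, normalized to unit
sum, and use reflected boundaries, so constants are fixed points and the
trace mean is conserved away from edges. Event onsets are the first bins of
maximal significant runs — a repository convention, since only "onset" is
specified. Ensemble–SCE coupling smooths both binary traces with a 1-s
Gaussian, correlates them, and compares against the mean of 50 circular
rotations of the activation trace.

## The synthetic-data generator

`generate_experiment()` emulates the statistical structure the analyses
assume, with ground truth recorded for every planted feature:

- **Transient model.** Per-cell Poisson events (baseline 2 transients/min)
  convolved with a unit-peak exponential decay kernel (time constant 1 s,
  truncated at 4 time constants so the channel is exactly zero away from
  events); the noiseless convolution is the deconvolved-transient channel,
  and Gaussian noise (SD 0.2 in units of the unit transient peak) is added
  for the denoised trace.
- **Context coding.** 30% of cells, split evenly between contexts, receive
  an additive offset during their context's trials. Under the divergence
  scenario the offset follows a non-decreasing per-day schedule, by default
  a linear ramp from 0 to 3x the noise SD over the training days; under
  the null scenario it is identically zero.
- **Ensembles.** Planted member sets (default 15 cells, disjoint from
  coding cells) receive a shared event of amplitude 3x the noise SD at the
  start of randomly chosen 1-s windows inside their context's trials (5%
  of candidate windows). The ground truth records both the event windows
  and the *influence windows* — the event window plus one window per decay
  constant — because the planted bump genuinely persists in the trace for
  the kernel's duration; recovery tests measure recall against event
  windows and precision against influence windows.
- **Synchrony events.** At planted SCE windows, 60% of all cells receive an
  event, producing population-synchrony modes; `ensembles_in_sce` confines
  the tagged ensemble's activations to these windows to emulate SCE-locked
  reactivation.
- **Probe reinstatement.** Training days follow the divergence schedule;
  the probe session's trials alternate VEH/C21, with the tagged ensemble
  activating in 10% of C21-trial windows against 2% in VEH trials, and the
  non-tagged ensemble at 4% in both.
- **Registration.** Cells carry global ids; per-day detection subsamples at
  `overlap_fraction`, and registration maps are exact on shared cells.
- **Behavior.** Piecewise-linear waypoint paths route through both reward
  wells once per trial; options produce a stationary animal (speed exactly
  zero), zone-avoiding paths (waypoints confined to a convex region
  disjoint from both well boxes), and SCE-locked slowing (velocities scaled
  down for 2 s after each synchrony bin — zone entries are then no longer
  guaranteed, so the two options are exercised separately).
- **Seeding.** One master seed; every component draws from a child
  generator derived by hashing the master seed with a purpose string, so a
  given configuration reproduces bit-identically and components are
  independently reproducible.

What the generator does *not* emulate: place-field spatial tuning, slow
drift in baseline fluorescence, crosstalk between nearby sources,
registration errors, or realistic behavioral statistics. Passing the
recovery tests therefore demonstrates that the statistics detect the
structures they claim to detect at realistic effect sizes — not that real
recordings satisfy the generator's independence assumptions.

## Calibration conditions

The null-calibration checks run the generator with planted ensembles and
synchrony events switched off (`n_ensembles = 0`, `n_sce = 0`) in addition
to the zero separation schedule: each statistic's null condition is the
absence of *its* signal, and planted synchrony is genuine correlation
structure that the NCM and ensemble statistics are right to report. The
white-noise ensemble calibration uses iid Gaussian sessions, the strictest
structureless case.

## Problem sizes

Tests and the acceptance script run the generator at 60–100 cells, 1–5
days, 6–8 trials of 15–50 s — the scale at which every property (oracle
equivalence, null calibration, planted-effect recovery, reinstatement
direction, SCE coupling, byte-level determinism) is verifiable in a few
minutes on one CPU. The latent-space computations run at $N \le 3$
dimensions, where the KDE grid ($O((20/h)^N)$ points) is exact and fast;
the statistics' calibration and monotonicity properties are
dimension-generic, and the `n_dims` argument accepts 5 for full-scale use.

## Known limitations

- The KDE grid in 5 dimensions is expensive at small kernel sizes; the
  Monte-Carlo estimator is the practical alternative there.
- The eigenvalue null calibrates the *largest* coactivity mode; secondary
  planted ensembles with near-equal eigenvalues mix within their shared
  eigenspace (rotational degeneracy), so loading recovery is cleanest for
  ensembles whose eigenvalues are well separated.
- Circular-rotation nulls assume approximate stationarity within the kept
  (concatenated) bins; strong nonstationarity would inflate the NCM.
- The reward-zone box rule assumes well-centered boxes; if an upstream
  tracker anchors boxes differently, masks shift accordingly.
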