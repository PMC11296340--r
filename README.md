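# capop

Population-level analyses for longitudinal calcium imaging of the
hippocampus, built around the question of how the neural representation of
two behavioral contexts separates over training and re-emerges during
chemogenetic reactivation in a probe session.

The package is aimed at systems-neuroscience analysts working with
miniscope recordings that have already been through source extraction
(denoised fluorescence traces), spike deconvolution (transient time
courses), and cross-session cell registration. It provides the downstream
population statistics, a command-line pipeline over them, and — because such
recordings are rarely shareable — a synthetic-data generator that emulates
the multi-day, two-context experimental structure with known ground truth,
so every stage is testable by parameter recovery.

## What it computes

With $a_i \in \mathbb{R}^{cells}$ a population vector (PV) and $c_i$ its
context label:

- **PV distance ratio** (context separation in neural space): with cosine
  distance $d(a_i, a_j) = 1 - \frac{a_i \cdot a_j}{\|a_i\|\|a_j\|}$,

  $$D_{between}/D_{within} = \frac{(N_{c_1}^2 - N_{c_1} + N_{c_2}^2 - N_{c_2})
  \sum_{c_i \neq c_j} d(a_i,a_j)}{2 N_{c_1} N_{c_2} \sum_{i \neq j,\, c_i = c_j}
  d(a_i,a_j)}$$

  i.e. the mean ordered-pair distance between contexts over the mean within
  contexts, with a chance level from 10 random relabelings
  (`pv_distance_ratio`, `pv_ratio_chance`).
- **Latent-space distribution distance**: per-day PCA on 200-ms bins,
  projection on the first 5 PCs, z-scoring, Gaussian kernel density
  estimates per context with a cross-validated kernel size, and the
  symmetric Kullback–Leibler divergence
  $D = \sum_p P_1 \log\frac{P_1}{P_2} + \sum_p P_2 \log\frac{P_2}{P_1}$
  summed over a regular grid (`fit_latent_model`, `latent_kl_distance`).
- **Trajectory visualization**: Laplacian-eigenmap embedding of 1-s PVs
  (k-NN graph with $k = \lfloor m/10 \rfloor$, $L = D - A$) and linear
  time-warping of trials to 1000 samples (`spectral_embed`, `warp_trial`).
- **Cross-session PV similarity**: average activity vectors restricted to
  registered cells, z-scored across cells, compared per cell as
  $c_i = z_{i,1} z_{i,2}$ (`average_pv`, `pv_similarity`).
- **Normalized correlation matrix (NCM)**: pairwise Pearson correlations
  z-normalized against circular-rotation nulls, and per-cell NCM profile
  correlations across sessions (`ncm`, `ncm_similarity`).
- **Ensembles**: eigendecomposition of the population correlation matrix
  with a circular-shuffle eigenvalue null, activation scores
  $e_{i,t} = a_t \cdot e_i$ z-normalized against 1000 cell-identity
  shuffles, significant activation at $z > 2$, and probe-session activation
  rates per trial and ensemble group (`extract_ensembles`,
  `activation_scores`, `activation_rate`).
- **Synchronous calcium events (SCEs)**: smoothed fraction-active trace,
  significant bins at $z > 2$, coupling of ensemble activations to SCEs
  against a rotation null, and peri-event behavior averages (`detect_sce`,
  `ensemble_sce_correlation`, `peri_event_average`).

## Worked example

```r
library(capop)

cfg <- sim_config(n_cells = 60, n_days = 5, trials_per_day = 6,
                  trial_length = 15, seed = 1)
exp <- generate_experiment(cfg, "divergence")
exp$truth
#> <ground_truth> scenario 'divergence': 5 sessions, 2 ensembles, schedule 0/0.15/0.3/0.45/0.6

day5 <- exp$sessions[[5]]
mask <- build_mask(day5)           # reward-zone + outside-trial exclusions
mask
#> <analysis_mask> 356/510 bins kept; exclusions: reward_zone, outside_trial

pvs <- trial_pvs(day5, mask)       # one PV per trial
ratio <- pv_distance_ratio(pvs)
chance <- pv_ratio_chance(pvs, n_perm = 10, seed = 1)
sprintf("day 5 D-ratio: %.2f (shuffle chance %.2f +/- %.2f)", ratio,
        chance$mean, chance$sd)
#> "day 5 D-ratio: 11.46 (shuffle chance 1.92 +/- 3.35)"

es <- extract_ensembles(day5, context_mask(day5, mask, "C1"),
                        seed = 1, context = "C1")
es
#> <ensemble_set> 60 cells, 2 significant ensemble(s) of 60 (null 4.053 +/- 0.271), context C1

sce <- detect_sce(binarize_transients(day5$transients))
sce
#> <sce_series> 510 bins @ 5 Hz: 27 significant bins (z > 2), 3 event onset(s)
```

The day-5 D-ratio of 11.5 against a chance level near 1 reflects the
planted context separation (0.6 fluorescence units by day 5, 3x the noise
SD); the two significant ensembles are the planted coactive group plus the
planted synchrony mode, and the SCE detector flags the planted
population-synchrony windows.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/capop.R simulate --config config.yaml --seed 1 --out sim/
Rscript inst/cli/capop.R geometry --config config.yaml --seed 1 --in sim/ --out results/
```

Every result table carries `seed`, `config_hash` and `version` provenance
columns, and reruns with the same configuration and seed are byte-identical.

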