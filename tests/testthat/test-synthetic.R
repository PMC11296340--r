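test_that("identical config and scenario reproduce sessions bit-for-bit", {
  cfg <- sim_config(n_cells = 15, n_days = 2, trials_per_day = 4,
                    trial_length = 10, seed = 42)
  a <- generate_experiment(cfg, "divergence")
  b <- generate_experiment(cfg, "divergence")
  for (d in 1:2) {
    expect_identical(a$sessions[[d]]$traces, b$sessions[[d]]$traces)
    expect_identical(a$sessions[[d]]$transients, b$sessions[[d]]$transients)
    expect_identical(a$sessions[[d]]$behavior$head_xy,
                     b$sessions[[d]]$behavior$head_xy)
  }
  expect_identical(a$truth$sce_bins, b$truth$sce_bins)
})

test_that("config validation names the offending parameter", {
  expect_error(sim_config(n_cells = 1), "n_cells")
  expect_error(sim_config(overlap_fraction = 1.2), "overlap_fraction")
  expect_error(sim_config(noise_sd = NaN), "noise_sd")
  expect_error(sim_config(trials_per_day = 5), "trials_per_day")
  expect_error(
    generate_experiment(sim_config(n_days = 2, n_cells = 10),
                        "divergence", separation_schedule = c(1, 0.5)),
    "non-decreasing")
})

test_that("null scenario has a zero separation schedule; full overlap gives bijections", {
  cfg <- sim_config(n_cells = 20, n_days = 3, trials_per_day = 2,
                    trial_length = 5, overlap_fraction = 1, seed = 3)
  exp <- generate_experiment(cfg, "null")
  expect_equal(exp$truth$context_separation_per_day, rep(0, 3))
  for (r in exp$registration) {
    expect_equal(nrow(r$pairs), 20)
    expect_equal(sort(r$pairs$id_x), 1:20)
  }
  # partial overlap: maps are exact on shared cells
  cfg2 <- sim_config(n_cells = 20, n_days = 2, trials_per_day = 2,
                     trial_length = 5, overlap_fraction = 0.6, seed = 3)
  exp2 <- generate_experiment(cfg2, "null")
  shared <- intersect(exp2$sessions[[1]]$cell_ids,
                      exp2$sessions[[2]]$cell_ids)
  expect_equal(sort(exp2$registration[[1]]$pairs$id_x), sort(shared))
})

test_that("divergence schedule appears monotonically in the emitted traces", {
  cfg <- sim_config(n_cells = 40, n_days = 3, trials_per_day = 6,
                    trial_length = 15, seed = 1)
  exp <- generate_experiment(cfg, "divergence",
                             separation_schedule = c(0, 0.5, 1.0))
  diffs <- vapply(1:3, function(d) {
    s <- exp$sessions[[d]]
    pv <- trial_pvs(s, build_mask(s, "outside_trial"))
    m1 <- colMeans(pv$vectors[pv$labels == "C1", , drop = FALSE])
    m2 <- colMeans(pv$vectors[pv$labels == "C2", , drop = FALSE])
    mean(abs(m1 - m2))
  }, 0)
  expect_true(all(diff(diffs) > 0))
})

test_that("planted ensemble activations lie inside their context's trials", {
  cfg <- sim_config(n_cells = 50, n_days = 2, trials_per_day = 4,
                    trial_length = 10, seed = 8)
  exp <- generate_experiment(cfg, "divergence")
  for (e in exp$truth$ensembles) {
    for (d in seq_along(exp$sessions)) {
      tt <- exp$sessions[[d]]$trial_table
      rows <- which(tt$context_id == e$context)
      for (b in e$activation_bins[[d]]) {
        inside <- any(b > tt$start_bin[rows] & b <= tt$end_bin[rows])
        expect_true(inside)
      }
    }
  }
})

test_that("probe C21 trials carry more tagged-ensemble events than VEH trials", {
  cfg <- sim_config(n_cells = 50, n_days = 1, trials_per_day = 6,
                    trial_length = 30, seed = 5)
  exp <- generate_experiment(cfg, "probe_reinstatement")
  probe <- exp$sessions[[2]]
  tt <- probe$trial_table
  tagged <- exp$truth$ensembles[[1]]
  expect_true(tagged$tagged)
  counts <- vapply(c("C21", "VEH"), function(trt) {
    rows <- which(tt$treatment == trt)
    sum(vapply(tagged$activation_bins[[2]], function(b)
      any(b > tt$start_bin[rows] & b <= tt$end_bin[rows]), TRUE))
  }, 0)
  expect_gt(counts["C21"], counts["VEH"])
  expect_equal(exp$truth$treatment_labels, tt$treatment)
})

test_that("behavior options produce the requested regimes", {
  cfg <- sim_config(n_cells = 5, n_days = 1, trials_per_day = 4,
                    trial_length = 10, seed = 6)
  s <- generate_experiment(cfg, "null", behavior = FALSE)$sessions[[1]]
  # stationary: speed identically zero
  st <- generate_behavior(s, cfg, stationary = TRUE)
  expect_true(all(st$behavior$speed == 0))
  # default: at least one entry into each reward-zone box per trial
  dft <- generate_behavior(s, cfg)
  m <- build_mask(dft, "reward_zone")
  tt <- dft$trial_table
  for (i in seq_len(nrow(tt)))
    expect_true(any(m$reasons[(tt$start_bin[i] + 1):tt$end_bin[i],
                              "reward_zone"]))
  # no zone entries: reward-zone reason all false
  nz <- generate_behavior(s, cfg, zone_entries = FALSE)
  expect_false(any(build_mask(nz, "reward_zone")$reasons[, "reward_zone"]))
})

test_that("SCE-locked slowing lowers speed after planted events", {
  cfg <- sim_config(n_cells = 5, n_days = 1, trials_per_day = 6,
                    trial_length = 20, seed = 12)
  exp <- generate_experiment(cfg, "null", n_sce = 6, behavior = FALSE)
  s <- exp$sessions[[1]]
  sce_bins <- exp$truth$sce_bins[[1]]
  s <- generate_behavior(s, cfg, sce_locked_slowing = TRUE,
                         sce_bins = sce_bins)
  sp <- s$behavior$speed
  post <- unique(unlist(lapply(sce_bins, function(b)
    b:min(length(sp), b + 10))))
  expect_lt(mean(sp[post]), mean(sp[-post]))
})
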