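test_that("correlation eigenvalues conserve the trace and permute with cell order", {
  set.seed(3)
  s <- make_session(matrix(rnorm(20 * 400), 20))
  es <- extract_ensembles(s, keep_all_mask(s), n_shuffles = 20, seed = 1)
  expect_equal(sum(es$eigenvalues), 20, tolerance = 1e-8)
  # permuting cells permutes loadings and keeps eigenvalues
  perm <- sample(20)
  s2 <- ca_session(s$traces[perm, ], s$transients[perm, ], perm,
                   s$trial_table)
  es2 <- extract_ensembles(s2, keep_all_mask(s2), n_shuffles = 20, seed = 1)
  expect_equal(es2$eigenvalues, es$eigenvalues, tolerance = 1e-10)
  v1 <- es$vectors[perm, 1]
  expect_equal(abs(v1), abs(es2$vectors[, 1]), tolerance = 1e-8)
})

test_that("white-noise sessions yield at most a couple of significant ensembles", {
  counts <- vapply(1:5, function(i) {
    set.seed(100 + i)
    s <- make_session(matrix(rnorm(60 * 1500), 60))
    es <- extract_ensembles(s, keep_all_mask(s), n_shuffles = 50, seed = i)
    sum(es$significant)
  }, 0L)
  expect_lte(mean(counts), 2)
})

test_that("a planted coactive ensemble is recovered with high loading overlap", {
  for (seed in 1:3) {
    cfg <- sim_config(n_cells = 100, n_days = 1, trials_per_day = 8,
                      trial_length = 50, seed = seed)
    exp <- generate_experiment(cfg, "null", n_ensembles = 1, n_sce = 0)
    s <- exp$sessions[[1]]
    es <- extract_ensembles(s, build_mask(s), seed = seed)
    members <- exp$truth$ensembles[[1]]$members
    pat <- rep(0, length(es$cell_ids))
    pat[match(members, es$cell_ids)] <- 1
    pat <- pat / sqrt(sum(pat^2))
    expect_gte(sum(es$significant), 1)
    cs <- abs(crossprod(es$vectors[, which(es$significant), drop = FALSE],
                        pat))
    expect_gte(max(cs), 0.8)
  }
})

test_that("constant cells are excluded with a warning", {
  set.seed(4)
  tr <- rbind(matrix(rnorm(6 * 300), 6), rep(2, 300))
  s <- make_session(tr)
  expect_warning(es <- extract_ensembles(s, keep_all_mask(s),
                                         n_shuffles = 10, seed = 1),
                 "constant")
  expect_equal(length(es$cell_ids), 6)
  flat <- make_session(matrix(1, 5, 50))
  expect_error(extract_ensembles(flat, keep_all_mask(flat),
                                 n_shuffles = 5, seed = 1), "constant")
})

test_that("a uniform loading vector makes every cell-ID shuffle degenerate", {
  set.seed(6)
  s <- make_session(matrix(rnorm(10 * 300), 10))
  es <- extract_ensembles(s, keep_all_mask(s), n_shuffles = 10, seed = 1)
  es$vectors[, 1] <- 1 / sqrt(10)  # uniform loadings
  acts <- activation_scores(es, s, which_ensembles = 1, n_shuffles = 50,
                            seed = 2)
  expect_true(all(acts[[1]]$undefined))
  expect_true(all(is.na(acts[[1]]$scores)))
})

test_that("activation scoring is consistent under relabelled target ids", {
  cfg <- sim_config(n_cells = 40, n_days = 1, trials_per_day = 4,
                    trial_length = 20, seed = 9)
  exp <- generate_experiment(cfg, "null", n_ensembles = 1, n_sce = 0)
  s <- exp$sessions[[1]]
  es <- extract_ensembles(s, build_mask(s), n_shuffles = 30, seed = 1)
  a1 <- activation_scores(es, s, which_ensembles = 1, n_shuffles = 100,
                          seed = 3)[[1]]
  # relabel the target's cells; the registration map absorbs the change
  s2 <- ca_session(s$traces, s$transients, s$cell_ids + 1000,
                   s$trial_table, meta = s$meta)
  reg <- registration_map(data.frame(id_x = s$cell_ids,
                                     id_y = s$cell_ids + 1000))
  a2 <- activation_scores(es, s2, reg = reg, which_ensembles = 1,
                          n_shuffles = 100, seed = 3)[[1]]
  expect_equal(a2$scores, a1$scores)
  expect_equal(a2$raw, a1$raw)
})

test_that("planted activations are recovered and the null scenario stays quiet", {
  cfg <- sim_config(n_cells = 100, n_days = 1, trials_per_day = 8,
                    trial_length = 50, seed = 2)
  exp <- generate_experiment(cfg, "null", n_ensembles = 1, n_sce = 0)
  s <- exp$sessions[[1]]
  es <- extract_ensembles(s, build_mask(s), seed = 2)
  members <- exp$truth$ensembles[[1]]$members
  pat <- rep(0, length(es$cell_ids))
  pat[match(members, es$cell_ids)] <- 1
  pat <- pat / sqrt(sum(pat^2))
  sig <- which(es$significant)
  best <- sig[which.max(abs(crossprod(es$vectors[, sig, drop = FALSE],
                                      pat)))]
  a <- activation_scores(es, s, which_ensembles = best, seed = 2)[[1]]
  tw <- exp$truth$ensembles[[1]]$windows_1s[[1]]
  ext <- unique(unlist(exp$truth$ensembles[[1]]$influence_windows_1s[[1]]))
  sw <- a$bins_1s[a$significant]
  expect_gte(mean(tw %in% sw), 0.9)
  expect_gte(mean(sw %in% ext), 0.8)
  # null false-activation frequency: score a reference pattern on an
  # independent session; stays near the one-sided z > 2 tail
  rates <- vapply(1:5, function(seed) {
    cfgn <- sim_config(n_cells = 60, n_days = 2, trials_per_day = 6,
                       trial_length = 20, seed = seed)
    en <- generate_experiment(cfgn, "null", n_ensembles = 0, n_sce = 0)
    esn <- extract_ensembles(en$sessions[[1]], build_mask(en$sessions[[1]]),
                             n_shuffles = 30, seed = seed)
    # score day 1's top eigenvector on day 2, which shares no structure
    an <- activation_scores(esn, en$sessions[[2]], which_ensembles = 1,
                            n_shuffles = 300, seed = seed)[[1]]
    mean(an$significant)
  }, 0)
  expect_lte(mean(rates), 0.05)
})

test_that("activation rates normalize to the session total", {
  cfg <- sim_config(n_cells = 20, n_days = 1, trials_per_day = 4,
                    trial_length = 10, seed = 3)
  s <- generate_experiment(cfg, "null")$sessions[[1]]
  mk <- function(sig_windows) {
    structure(list(ensemble = 1, raw = numeric(0),
                   scores = rep(3, length(sig_windows)),
                   significant = rep(TRUE, length(sig_windows)),
                   undefined = rep(FALSE, length(sig_windows)),
                   bins_1s = sig_windows, bin_width = 1),
              class = "activation_series")
  }
  tt <- s$trial_table
  w_in_trial <- function(i) (tt$start_bin[i] / 5 + 1):(tt$end_bin[i] / 5)
  tagged <- mk(w_in_trial(1)[1:4])
  nont <- mk(w_in_trial(2)[1:4])
  r <- activation_rate(list(tagged, nont), c("tagged", "nontagged"), s)
  expect_equal(sum(r$fraction), 1)
  expect_equal(sum(r$fraction[r$group == "tagged"]), 0.5)
  r2 <- activation_rate(list(tagged), "tagged", s)
  expect_equal(sum(r2$fraction[r2$group == "tagged"]), 1)
  # zero activations: fractions undefined but reported
  r0 <- activation_rate(list(mk(integer(0))), "tagged", s)
  expect_true(all(is.na(r0$fraction)))
  expect_equal(unique(r0$total), 0)
})
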