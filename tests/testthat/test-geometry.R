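test_that("cosine distance follows 1 - cos(a, b)", {
  u <- c(0.3, -1, 2)
  expect_equal(cosine_distance(u, u), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 0), c(-1, 0)), 2)
  expect_error(cosine_distance(c(0, 0), c(1, 0)), "zero vector")
})

test_that("trial warping interpolates to exactly n evenly spaced samples", {
  tr <- matrix(rnorm(2000), ncol = 2)
  expect_equal(warp_trial(tr), tr)  # already length 1000
  seg <- warp_trial(rbind(c(0, 0), c(1, 1)))
  expect_equal(nrow(seg), 1000)
  expect_equal(seg[1, ], c(0, 0))
  expect_equal(seg[1000, ], c(1, 1))
  expect_equal(seg[, 1], seg[, 2])  # stays on the diagonal
  expect_equal(nrow(warp_trial(matrix(rnorm(14), ncol = 2))), 1000)
  expect_error(warp_trial(matrix(1, 1, 2)), "at least 2")
})

test_that("spectral embedding preserves cluster structure and matches a dense oracle", {
  set.seed(11)
  n <- 30
  x <- rbind(matrix(rnorm(n * 50), n), matrix(rnorm(n * 50, 1), n))
  lab <- rep(1:2, each = n)
  emb <- spectral_embed(x)
  expect_equal(dim(emb), c(60, 2))
  expect_gt(silhouette2(emb, lab), 0.5)
  # independent dense oracle: rebuild the k-NN-union Laplacian from scratch
  k <- nrow(x) %/% 10
  d <- as.matrix(dist(x))
  A <- matrix(0, nrow(x), nrow(x))
  for (i in seq_len(nrow(x)))
    A[i, order(d[i, ])[2:(k + 1)]] <- 1
  A <- 1 * ((A + t(A)) > 0)
  L <- diag(colSums(A)) - A
  eg <- eigen(L, symmetric = TRUE)
  ord <- order(eg$values)
  nz <- ord[eg$values[ord] > 1e-8][1:2]
  oracle <- eg$vectors[, nz]
  for (j in 1:2)
    expect_true(max(abs(emb[, j] - oracle[, j])) < 1e-6 ||
                max(abs(emb[, j] + oracle[, j])) < 1e-6)
})

test_that("spectral embedding is invariant to cell-order permutation and fails on disconnected graphs", {
  set.seed(2)
  x <- matrix(rnorm(40 * 20), 40)
  e1 <- spectral_embed(x)
  e2 <- spectral_embed(x[, sample(ncol(x))])
  for (j in 1:2)
    expect_true(max(abs(e1[, j] - e2[, j])) < 1e-8 ||
                max(abs(e1[, j] + e2[, j])) < 1e-8)
  # two far-apart cliques with k = 1 cannot be connected
  y <- rbind(matrix(rnorm(10 * 3, 0, 0.01), 10),
             matrix(rnorm(10 * 3, 100, 0.01), 10))
  expect_error(spectral_embed(y, k = 1), "disconnected")
  expect_error(spectral_embed(matrix(rnorm(10 * 3), 10)), "at least 20")
})

test_that("pv_distance_ratio implements the printed formula", {
  v <- rbind(c(1, 0), c(0.9, 0.1), c(0, 1), c(0.1, 0.9))
  lab <- c("C1", "C1", "C2", "C2")
  expect_equal(pv_distance_ratio(v, lab), brute_force_ratio(v, lab),
               tolerance = 1e-12)
  # label swap symmetry
  lab2 <- ifelse(lab == "C1", "C2", "C1")
  expect_equal(pv_distance_ratio(v, lab), pv_distance_ratio(v, lab2))
  # degenerate within-context distances
  w <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_error(pv_distance_ratio(w, lab), "degenerate")
  expect_error(pv_distance_ratio(v, c("C1", "C1", "C1", "C1")),
               "two contexts")
})

test_that("ratio chance is reproducible and near 1 for exchangeable contexts", {
  set.seed(21)
  v <- matrix(abs(rnorm(20 * 12, 2)), 20)
  lab <- rep(c("C1", "C2"), 10)
  c1 <- pv_ratio_chance(v, lab, n_perm = 10, seed = 5)
  c2 <- pv_ratio_chance(v, lab, n_perm = 10, seed = 5)
  expect_identical(c1$values, c2$values)
  expect_lt(abs(pv_distance_ratio(v, lab) - c1$mean), 3 * c1$sd)
})

test_that("latent model z-scores its scores and selects interior kernels", {
  cfg <- sim_config(n_cells = 30, n_days = 2, trials_per_day = 4,
                    trial_length = 20, seed = 13)
  exp <- generate_experiment(cfg, "null")
  masks <- lapply(exp$sessions, build_mask)
  model <- fit_latent_model(exp$sessions, masks, n_dims = 3, seed = 3)
  pr <- project_latent(model, 1, exp$sessions[[1]], masks[[1]])
  expect_equal(colMeans(pr$scores), rep(0, 3), tolerance = 1e-8)
  expect_equal(apply(pr$scores, 2, sd), rep(1, 3), tolerance = 1e-8)
  grid <- model$kernel_grid
  for (d in model$days)
    expect_true(d$h_opt > grid[1] && d$h_opt < grid[length(grid)])
  # two identical days give identical per-day optima
  model2 <- fit_latent_model(list(exp$sessions[[1]], exp$sessions[[1]]),
                             list(masks[[1]], masks[[1]]), n_dims = 3,
                             seed = 3)
  hs <- vapply(model2$days, `[[`, 0, "h_opt")
  expect_equal(hs[1], hs[2])
  expect_equal(model2$kernel_size, hs[1])
  expect_error(fit_latent_model(exp$sessions[1],
                                list(keep_all_mask(exp$sessions[[1]])),
                                cv_folds = 1e6), "folds")
})

test_that("latent KL is zero at identity, symmetric, and increases with separation", {
  model <- structure(list(kernel_size = 0.4, n_dims = 1,
                          days = list(), kernel_grid = NULL),
                     class = "latent_model")
  set.seed(31)
  x <- matrix(rnorm(500), ncol = 1)
  expect_equal(latent_kl_distance(model, x, x), 0)
  y <- matrix(rnorm(500, 1), ncol = 1)
  expect_equal(latent_kl_distance(model, x, y),
               latent_kl_distance(model, y, x))
  kls <- vapply(c(0, 1, 2), function(delta)
    latent_kl_distance(model, x, matrix(rnorm(500, delta), ncol = 1)), 0)
  expect_true(all(diff(kls) > 0))
  expect_true(all(kls >= 0))
  expect_error(latent_kl_distance(model, x[0, , drop = FALSE], y),
               "non-empty")
  bad <- model; bad$kernel_size <- 0
  expect_error(latent_kl_distance(bad, x, y), "kernel_size")
})

test_that("grid KL agrees with the Monte-Carlo estimator", {
  model <- structure(list(kernel_size = 0.5, n_dims = 2),
                     class = "latent_model")
  set.seed(41)
  x <- matrix(rnorm(600), ncol = 2)
  y <- matrix(rnorm(600, 0.8), ncol = 2)
  g <- latent_kl_distance(model, x, y)
  mc <- latent_kl_mc(model, x, y, n_mc = 4000, seed = 2)
  expect_equal(g, mc, tolerance = 0.15)
})

test_that("latent KL chance is reproducible and brackets the null statistic", {
  cfg <- sim_config(n_cells = 30, n_days = 1, trials_per_day = 6,
                    trial_length = 15, seed = 17)
  exp <- generate_experiment(cfg, "null", n_sce = 0, n_ensembles = 0)
  s <- exp$sessions[[1]]
  mask <- build_mask(s)
  model <- fit_latent_model(list(s), list(mask), n_dims = 2, seed = 3)
  pr <- project_latent(model, 1, s, mask)
  kl <- latent_kl_distance(model, pr$scores[pr$labels == "C1", ],
                           pr$scores[pr$labels == "C2", ])
  ch <- latent_kl_chance(model, pr$scores, pr$labels, pr$trial,
                         n_perm = 10, seed = 4)
  ch2 <- latent_kl_chance(model, pr$scores, pr$labels, pr$trial,
                          n_perm = 10, seed = 4)
  expect_identical(ch$values, ch2$values)
  expect_lt(abs(kl - ch$mean), 3 * ch$sd)
})
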