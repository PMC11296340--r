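#' Population vectors over fixed-width time bins
#'
#' Averages the denoised traces within consecutive `bin_width`-second bins.
#' A bin contributes a row only if every constituent sample is kept by the
#' mask; each row is labeled with the context of the covering trial.
#'
#' @param session a `ca_session`.
#' @param mask an `analysis_mask` (default: keep everything in-trial).
#' @param bin_width bin width in seconds (default 1).
#' @return a `pv_series`: list with `vectors` (m x cells), `labels`,
#'   `trial` (per-row trial index) and `bin_width`.
#' @export
population_vectors <- function(session,
                               mask = build_mask(session, "outside_trial"),
                               bin_width = 1) {
  r <- session$meta$sample_rate
  per <- round(bin_width * r)
  nb <- n_bins(session)
  tt <- session$trial_table
  ctx_of_bin <- rep(NA_character_, nb)
  trial_of_bin <- rep(NA_integer_, nb)
  for (i in seq_len(nrow(tt))) {
    idx <- (tt$start_bin[i] + 1):tt$end_bin[i]
    ctx_of_bin[idx] <- tt$context_id[i]
    trial_of_bin[idx] <- i
  }
  n_out <- nb %/% per
  vecs <- NULL; labels <- character(0); trial <- integer(0)
  rows <- list()
  for (j in seq_len(n_out)) {
    idx <- ((j - 1) * per + 1):(j * per)
    if (!all(mask$keep[idx])) next
    tr <- unique(trial_of_bin[idx])
    if (length(tr) != 1 || is.na(tr)) next
    rows[[length(rows) + 1]] <- list(
      v = rowMeans(session$traces[, idx, drop = FALSE]),
      lab = ctx_of_bin[idx[1]], trial = tr)
  }
  structure(list(
    vectors = do.call(rbind, lapply(rows, `[[`, "v")),
    labels = vapply(rows, `[[`, "", "lab"),
    trial = vapply(rows, `[[`, 0L, "trial"),
    bin_width = bin_width,
    mask_applied = mask$exclusions), class = "pv_series")
}

#' Trial-averaged population vectors
#'
#' One PV per trial: the per-cell average of the denoised trace over the
#' trial's kept bins (reward-zone bins excluded under the default training
#' mask).
#'
#' @inheritParams population_vectors
#' @return a `pv_series` with one row per trial with at least one kept bin.
#' @export
trial_pvs <- function(session, mask = build_mask(session)) {
  tt <- session$trial_table
  rows <- list()
  for (i in seq_len(nrow(tt))) {
    idx <- (tt$start_bin[i] + 1):tt$end_bin[i]
    idx <- idx[mask$keep[idx]]
    if (length(idx) == 0) next
    rows[[length(rows) + 1]] <- list(
      v = rowMeans(session$traces[, idx, drop = FALSE]),
      lab = tt$context_id[i], trial = i)
  }
  structure(list(
    vectors = do.call(rbind, lapply(rows, `[[`, "v")),
    labels = vapply(rows, `[[`, "", "lab"),
    trial = vapply(rows, `[[`, 0L, "trial"),
    bin_width = NA_real_,
    mask_applied = mask$exclusions), class = "pv_series")
}

#' @export
print.pv_series <- function(x, ...) {
  cat(sprintf("<pv_series> %d PVs x %d cells; contexts: %s\n",
              nrow(x$vectors), ncol(x$vectors),
              paste(names(table(x$labels)), collapse = "/")))
  invisible(x)
}

#' Spectral embedding of population vectors
#'
#' Laplacian-eigenmap reduction to two dimensions. An undirected k-nearest-
#' neighbor graph is built over the rows (k = floor(m/10), neighbor relation
#' symmetrized by union, unweighted edges), the unnormalized graph Laplacian
#' L = D - A is eigen-decomposed, and the rows are projected on the two
#' eigenvectors with the smallest nonzero eigenvalues.
#'
#' @param x numeric matrix (m x cells) or a `pv_series`.
#' @param k neighbor count; default floor(m/10).
#' @return m x 2 coordinate matrix.
#' @export
spectral_embed <- function(x, k = NULL) {
  if (inherits(x, "pv_series")) x <- x$vectors
  m <- nrow(x)
  if (m < 20) stop("spectral_embed: need at least 20 population vectors")
  k <- k %||% (m %/% 10)
  if (k < 1) stop("spectral_embed: k must be >= 1")
  dmat <- as.matrix(stats::dist(x))
  A <- matrix(0, m, m)
  for (i in seq_len(m)) {
    nn <- order(dmat[i, ])[2:(k + 1)]  # skip self
    A[i, nn] <- 1
  }
  A <- pmax(A, t(A))  # union symmetrization
  L <- diag(rowSums(A)) - A
  eg <- eigen(L, symmetric = TRUE)
  vals <- rev(eg$values)
  vecs <- eg$vectors[, ncol(eg$vectors):1, drop = FALSE]
  tol <- max(abs(vals)) * 1e-8
  nz <- which(vals > tol)
  if (length(nz) == 0 || nz[1] > 2)
    stop("spectral_embed: k-NN graph is disconnected; increase k")
  vecs[, nz[1:2], drop = FALSE]
}

#' Warp a trajectory to a fixed number of evenly spaced samples
#'
#' Linear interpolation at `n_samples` evenly spaced positions from the first
#' to the last sample; endpoints are preserved exactly. Used to overlay
#' variable-length trial trajectories.
#'
#' @param traj t x d numeric matrix (t >= 2).
#' @param n_samples number of output samples (default 1000).
#' @return n_samples x d matrix.
#' @export
warp_trial <- function(traj, n_samples = 1000) {
  if (is.vector(traj)) traj <- matrix(traj, ncol = 1)
  t_in <- nrow(traj)
  if (t_in < 2) stop("warp_trial: need at least 2 samples")
  xout <- seq(1, t_in, length.out = n_samples)
  apply(traj, 2, function(col) approx(seq_len(t_in), col, xout)$y)
}

#' Cosine distance between two vectors
#'
#' d(a, b) = 1 - (a . b) / (||a|| ||b||), in [0, 2].
#'
#' @param a,b nonzero numeric vectors of equal length.
#' @return the cosine distance.
#' @export
cosine_distance <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine_distance: zero vector")
  1 - sum(a * b) / (na * nb)
}

cosine_distance_matrix <- function(v) {
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0)) stop("cosine distance: zero vector among PVs")
  d <- 1 - tcrossprod(v / nrm)
  diag(d) <- 0
  d
}

#' Between/within-context population-vector distance ratio
#'
#' The separation of the two context representations in neural space:
#' the ratio of the average pairwise cosine distance between PVs of different
#' contexts to the average pairwise distance within a context,
#' \deqn{D_{between}/D_{within} = \frac{(N_{c1}^2 - N_{c1} + N_{c2}^2 -
#'   N_{c2}) \sum_{c_i \neq c_j} d(a_i, a_j)}{2 N_{c1} N_{c2}
#'   \sum_{i \neq j, c_i = c_j} d(a_i, a_j)}}
#' which equals the ratio of the mean over ordered different-context pairs to
#' the mean over ordered same-context pairs.
#'
#' @param pvs a `pv_series` (typically from [trial_pvs()]) or an m x cells
#'   matrix.
#' @param labels context label per row (taken from `pvs` if a `pv_series`).
#' @return the distance ratio (1 under exchangeable contexts).
#' @export
pv_distance_ratio <- function(pvs, labels = NULL) {
  if (inherits(pvs, "pv_series")) { labels <- pvs$labels; pvs <- pvs$vectors }
  stopifnot(is.matrix(pvs), length(labels) == nrow(pvs))
  ctx <- sort(unique(labels))
  if (length(ctx) != 2)
    stop("pv_distance_ratio: exactly two contexts required")
  n1 <- sum(labels == ctx[1]); n2 <- sum(labels == ctx[2])
  if (n1 < 2 || n2 < 2)
    stop("pv_distance_ratio: need at least 2 PVs per context")
  d <- cosine_distance_matrix(pvs)
  same <- outer(labels, labels, "==")
  sum_between <- sum(d[!same])
  sum_within <- sum(d[same & !diag(nrow(d))])
  if (sum_within == 0)
    stop("pv_distance_ratio: degenerate input, within-context distances are all zero")
  ((n1^2 - n1 + n2^2 - n2) * sum_between) / (2 * n1 * n2 * sum_within)
}

#' Chance level of the PV distance ratio by label permutation
#'
#' Repeats [pv_distance_ratio()] with randomly permuted context identities
#' (trial-level permutation) and averages across permutations.
#'
#' @inheritParams pv_distance_ratio
#' @param n_perm number of permutations (default 10).
#' @param seed integer seed.
#' @return list with `mean`, `sd` and the per-permutation `values`.
#' @export
pv_ratio_chance <- function(pvs, labels = NULL, n_perm = 10, seed = 1) {
  if (inherits(pvs, "pv_series")) { labels <- pvs$labels; pvs <- pvs$vectors }
  vals <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    pv_distance_ratio(pvs, sample(labels)), 0))
  list(mean = mean(vals), sd = sd(vals), values = vals)
}

# ---- latent-space distribution distance -----------------------------------

# Gaussian product-kernel density of sample X evaluated at points Y
# (shared bandwidth h), computed in chunks to bound memory.
kde_density <- function(Y, X, h, log = FALSE, chunk = 4000L) {
  d <- ncol(X)
  const <- -0.5 * d * log(2 * pi * h^2)
  out <- numeric(nrow(Y))
  x2 <- rowSums(X^2)
  for (i0 in seq(1, nrow(Y), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(Y))
    Yc <- Y[i0:i1, , drop = FALSE]
    nr <- i1 - i0 + 1L
    lk <- tcrossprod(Yc, X)
    lk <- sweep(lk, 2L, x2 / 2, "-") - rowSums(Yc^2) / 2  # -d^2/2, recycled
    lk <- lk / h^2
    if (log) {
      # shift by the row maximum (via max.col) for numerical stability
      mx <- lk[cbind(seq_len(nr), max.col(lk))]
      out[i0:i1] <- const + mx + base::log(.rowMeans(exp(lk - mx), nr,
                                                     nrow(X)))
    } else {
      # densities that underflow to 0 are handled by the caller's floor
      out[i0:i1] <- exp(const) * .rowMeans(exp(lk), nr, nrow(X))
    }
  }
  out
}

#' Fit the latent-space model: per-day PCA and cross-validated kernel size
#'
#' For each training day, PCA is computed on the day's 200-ms population
#' vectors (reward-zone bins excluded); each bin is projected on the first
#' `n_dims` principal components and the scores are z-scored per dimension.
#' The Gaussian-KDE kernel size is selected per day by maximizing held-out
#' log-likelihood in a k-fold cross-validation over a log-spaced grid, run on
#' a random subsample of the bins; the final kernel size is the mean of the
#' per-day optima.
#'
#' @param sessions list of `ca_session` (one per training day).
#' @param masks list of `analysis_mask`, parallel to `sessions` (default:
#'   training exclusions).
#' @param n_dims latent dimensionality (default 5).
#' @param cv_folds folds for kernel cross-validation (default 4).
#' @param subsample fraction of bins used in the CV (default 0.10).
#' @param kernel_grid candidate kernel sizes in z-units (default 15
#'   log-spaced values in [0.05, 2]).
#' @param seed integer seed for the CV subsample and fold assignment.
#' @return a `latent_model`: per-day projections and z parameters,
#'   per-day optimal kernels, and the averaged `kernel_size`.
#' @export
fit_latent_model <- function(sessions, masks = NULL, n_dims = 5,
                             cv_folds = 4, subsample = 0.10,
                             kernel_grid = exp(seq(log(0.05), log(2),
                                                   length.out = 15)),
                             seed = 1) {
  if (inherits(sessions, "ca_session")) sessions <- list(sessions)
  masks <- masks %||% lapply(sessions, build_mask)
  days <- vector("list", length(sessions))
  for (d in seq_along(sessions)) {
    s <- sessions[[d]]; mask <- masks[[d]]
    X <- t(s$traces[, mask$keep, drop = FALSE])
    if (nrow(X) < cv_folds)
      stop("fit_latent_model: fewer usable bins than folds")
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    nd <- min(n_dims, ncol(pc$rotation))
    sc <- pc$x[, seq_len(nd), drop = FALSE]
    zmu <- colMeans(sc); zsd <- apply(sc, 2, sd)
    if (any(zsd == 0))
      stop("fit_latent_model: degenerate latent dimension (zero variance)")
    z <- sweep(sweep(sc, 2, zmu), 2, zsd, "/")
    cv <- with_seed(child_seed(seed, "latent-cv"), {
      n_sub <- max(cv_folds, round(subsample * nrow(z)))
      sub <- z[sample.int(nrow(z), n_sub), , drop = FALSE]
      fold <- sample(rep_len(seq_len(cv_folds), n_sub))
      ll <- vapply(kernel_grid, function(h) {
        sum(vapply(seq_len(cv_folds), function(f) {
          tr <- sub[fold != f, , drop = FALSE]
          te <- sub[fold == f, , drop = FALSE]
          sum(kde_density(te, tr, h, log = TRUE))
        }, 0))
      }, 0)
      list(loglik = ll, h_opt = kernel_grid[which.max(ll)])
    })
    days[[d]] <- list(rotation = pc$rotation[, seq_len(nd), drop = FALSE],
                      center = pc$center, z_mean = zmu, z_sd = zsd,
                      cell_ids = s$cell_ids, h_opt = cv$h_opt,
                      cv_loglik = cv$loglik)
  }
  structure(list(days = days, n_dims = n_dims,
                 kernel_grid = kernel_grid,
                 kernel_size = mean(vapply(days, `[[`, 0, "h_opt"))),
            class = "latent_model")
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("<latent_model> %d day(s), %d latent dims, kernel size %.3f (per-day: %s)\n",
              length(x$days), x$n_dims, x$kernel_size,
              paste(signif(vapply(x$days, `[[`, 0, "h_opt"), 3),
                    collapse = "/")))
  invisible(x)
}

#' Project a session's bins into the fitted latent space
#'
#' @param model a `latent_model`.
#' @param day day index into the model.
#' @param session the corresponding `ca_session`.
#' @param mask `analysis_mask` for the session.
#' @return list with z-scored `scores` (bins x n_dims), per-bin context
#'   `labels`, and per-bin `trial` index.
#' @export
project_latent <- function(model, day, session, mask = build_mask(session)) {
  dm <- model$days[[day]]
  stopifnot(identical(dm$cell_ids, session$cell_ids))
  keep <- which(mask$keep)
  X <- t(session$traces[, keep, drop = FALSE])
  sc <- sweep(X, 2, dm$center) %*% dm$rotation
  z <- sweep(sweep(sc, 2, dm$z_mean), 2, dm$z_sd, "/")
  dimnames(z) <- NULL
  tt <- session$trial_table
  nb <- n_bins(session)
  ctx <- rep(NA_character_, nb); tri <- rep(NA_integer_, nb)
  for (i in seq_len(nrow(tt))) {
    idx <- (tt$start_bin[i] + 1):tt$end_bin[i]
    ctx[idx] <- tt$context_id[i]; tri[idx] <- i
  }
  list(scores = z, labels = ctx[keep], trial = tri[keep])
}

#' Symmetric Kullback-Leibler distance between two latent distributions
#'
#' Gaussian-KDE densities for the two samples are evaluated on a regular grid
#' spanning [-10, 10] per dimension with spacing equal to the model's
#' cross-validated kernel size, normalized to sum to one over the grid,
#' floored at `eps`, and combined as
#' D = sum P1 log(P1/P2) + sum P2 log(P2/P1).
#'
#' @param model a `latent_model` (supplies `kernel_size`).
#' @param scores1,scores2 score matrices (bins x dims) for the two contexts.
#' @param n_dims dimensions used (default: min of model and data; grids in
#'   more than 3 dimensions are large — see the package vignette).
#' @param eps density floor applied before taking logarithms.
#' @return non-negative symmetric divergence; 0 iff the two grid densities
#'   coincide.
#' @export
latent_kl_distance <- function(model, scores1, scores2,
                               n_dims = NULL, eps = 1e-12) {
  h <- model$kernel_size
  if (!is.numeric(h) || h <= 0)
    stop("latent_kl_distance: kernel_size must be positive")
  n_dims <- n_dims %||% min(model$n_dims, ncol(scores1))
  s1 <- as.matrix(scores1)[, seq_len(n_dims), drop = FALSE]
  s2 <- as.matrix(scores2)[, seq_len(n_dims), drop = FALSE]
  if (nrow(s1) == 0 || nrow(s2) == 0)
    stop("latent_kl_distance: both samples must be non-empty")
  ax <- seq(-10, 10, by = h)
  # Grid points farther than 12 kernel widths from every sample have
  # normalized densities far below the floor on both sides, so they
  # contribute exactly 0 to the floored KL sums; drop them up front.
  axes <- lapply(seq_len(n_dims), function(d) {
    rng <- range(s1[, d], s2[, d])
    ax[ax >= rng[1] - 12 * h & ax <= rng[2] + 12 * h]
  })
  grid <- as.matrix(do.call(expand.grid, axes))
  p1 <- kde_density(grid, s1, h); p1 <- p1 / sum(p1)
  p2 <- kde_density(grid, s2, h); p2 <- p2 / sum(p2)
  p1 <- pmax(p1, eps); p2 <- pmax(p2, eps)
  sum(p1 * log(p1 / p2)) + sum(p2 * log(p2 / p1))
}

#' Monte-Carlo cross-check of the latent KL distance
#'
#' Estimates the same symmetric divergence by sampling from the two kernel
#' densities instead of summing over a grid; used as an independent check of
#' the grid computation.
#'
#' @inheritParams latent_kl_distance
#' @param n_mc Monte-Carlo sample size per side.
#' @param seed integer seed.
#' @return estimate of the symmetric KL divergence.
#' @export
latent_kl_mc <- function(model, scores1, scores2, n_dims = NULL,
                         n_mc = 2000, seed = 1, eps = 1e-12) {
  h <- model$kernel_size
  n_dims <- n_dims %||% min(model$n_dims, ncol(scores1))
  s1 <- as.matrix(scores1)[, seq_len(n_dims), drop = FALSE]
  s2 <- as.matrix(scores2)[, seq_len(n_dims), drop = FALSE]
  with_seed(seed, {
    draw <- function(s) s[sample.int(nrow(s), n_mc, replace = TRUE), ,
                          drop = FALSE] +
      matrix(rnorm(n_mc * n_dims, 0, h), n_mc, n_dims)
    x1 <- draw(s1); x2 <- draw(s2)
    l1 <- function(y) pmax(kde_density(y, s1, h), eps)
    l2 <- function(y) pmax(kde_density(y, s2, h), eps)
    mean(log(l1(x1) / l2(x1))) + mean(log(l2(x2) / l1(x2)))
  })
}

#' Chance level of the latent KL distance by context-label permutation
#'
#' Permutes context identity at trial granularity (preserving within-trial
#' autocorrelation), recomputes [latent_kl_distance()] for each permutation,
#' and reports the permutation mean, SD and values.
#'
#' @param model a `latent_model`.
#' @param scores bins x dims score matrix (both contexts pooled).
#' @param labels per-bin context label.
#' @param trial per-bin trial index.
#' @param n_perm permutations (default 10).
#' @param seed integer seed.
#' @inheritParams latent_kl_distance
#' @return list with `mean`, `sd`, `values`.
#' @export
latent_kl_chance <- function(model, scores, labels, trial, n_perm = 10,
                             seed = 1, n_dims = NULL) {
  trials <- sort(unique(trial))
  tl <- vapply(trials, function(t) labels[match(t, trial)], "")
  ctx <- sort(unique(labels))
  if (length(ctx) != 2)
    stop("latent_kl_chance: exactly two labels required")
  vals <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm <- sample(tl)
    lab_i <- perm[match(trial, trials)]
    latent_kl_distance(model, scores[lab_i == ctx[1], , drop = FALSE],
                       scores[lab_i == ctx[2], , drop = FALSE],
                       n_dims = n_dims)
  }, 0))
  list(mean = mean(vals), sd = sd(vals), values = vals)
}
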