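#' Extract coactivity ensembles from a reference session
#'
#' Eigen-decomposes the Pearson correlation matrix of the population activity
#' on the kept bins. A null distribution of eigenvalues is built by circularly
#' shuffling every cell's trace independently and eigen-decomposing the
#' shuffled correlation matrices, keeping each shuffle's largest eigenvalue
#' (the noise-floor summary that calibrates the test: for structureless
#' activity the full spectrum always places ~15% of its mass above its own
#' mean + 1 SD, whereas the largest shuffled eigenvalue tracks the spectral
#' edge that genuine coactivity must exceed). An eigenvector is a significant
#' ensemble when its eigenvalue exceeds the null mean by more than one null
#' SD. Loading vectors are unit-norm with the sign convention that the
#' largest-magnitude loading is positive.
#'
#' @param session a `ca_session` (>= 5 cells).
#' @param mask an `analysis_mask`; kept bins should be at least the number of
#'   cells.
#' @param n_shuffles circular shuffles for the eigenvalue null (default 100).
#' @param seed integer seed.
#' @param context optional context tag stored with the set (extraction is
#'   typically run on each context's bins separately, via the mask).
#' @return an `ensemble_set`: eigenvectors (cells x k), eigenvalues, null
#'   mean/SD, significance flags, included cell ids.
#' @export
extract_ensembles <- function(session, mask = build_mask(session),
                              n_shuffles = 100, seed = 1,
                              context = NA_character_) {
  keep <- which(mask$keep)
  X <- session$traces[, keep, drop = FALSE]
  const <- apply(X, 1, function(r) pop_sd(r) == 0)
  if (all(const)) stop("extract_ensembles: all cells constant on kept bins")
  if (any(const))
    warning(sprintf("extract_ensembles: excluding %d constant cell(s)",
                    sum(const)))
  X <- X[!const, , drop = FALSE]
  ids <- session$cell_ids[!const]
  nc <- nrow(X); nb <- ncol(X)
  if (nc < 5) stop("extract_ensembles: need at least 5 cells")
  if (nb < nc)
    warning("extract_ensembles: fewer kept bins than cells; correlation matrix is rank-deficient")
  C <- cor(t(X))
  eg <- eigen(C, symmetric = TRUE)
  null_vals <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      shifts <- sample.int(nb - 1, nc, replace = TRUE)
      Xs <- X
      for (i in seq_len(nc)) Xs[i, ] <- circular_shift(X[i, ], shifts[i])
      max(eigen(cor(t(Xs)), symmetric = TRUE, only.values = TRUE)$values)
    }, 0)
  })
  null_mean <- mean(null_vals); null_sd <- sd(null_vals)
  vecs <- eg$vectors
  for (j in seq_len(ncol(vecs))) {
    i_max <- which.max(abs(vecs[, j]))
    if (vecs[i_max, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(cell_ids = ids, vectors = vecs, eigenvalues = eg$values,
                 null_mean = null_mean, null_sd = null_sd,
                 significant = eg$values > null_mean + null_sd,
                 n_shuffles = n_shuffles, context = context,
                 reference = list(mouse = session$meta$mouse,
                                  day = session$meta$day)),
            class = "ensemble_set")
}

#' @export
print.ensemble_set <- function(x, ...) {
  cat(sprintf("<ensemble_set> %d cells, %d significant ensemble(s) of %d (null %.3f +/- %.3f)%s\n",
              length(x$cell_ids), sum(x$significant), length(x$eigenvalues),
              x$null_mean, x$null_sd,
              if (is.na(x$context)) "" else paste0(", context ", x$context)))
  invisible(x)
}

# 1-s binned, per-cell z-scored activity of a session; a 1-s bin is kept
# only when all constituent samples are kept by the mask.
binned_activity <- function(session, mask = keep_all_mask(session),
                            bin_width = 1) {
  r <- session$meta$sample_rate
  per <- round(bin_width * r)
  nb <- n_bins(session)
  n_out <- nb %/% per
  kept <- vapply(seq_len(n_out), function(j)
    all(mask$keep[((j - 1) * per + 1):(j * per)]), TRUE)
  A <- vapply(which(kept), function(j)
    rowMeans(session$traces[, ((j - 1) * per + 1):(j * per), drop = FALSE]),
    numeric(nrow(session$traces)))
  A <- t(matrix(A, nrow = nrow(session$traces)))
  mu <- colMeans(A)
  sdv <- apply(A, 2, sd)
  sdv[sdv == 0] <- 1  # constant cells carry no signal; leave centered at 0
  list(z = sweep(sweep(A, 2, mu), 2, sdv, "/"),
       bins_1s = which(kept), per = per)
}

#' Ensemble activation scores in a target session
#'
#' Downsamples the target session into 1-s bins, restricts each significant
#' ensemble's loading vector to the cells shared with the target (re-
#' normalized to unit norm), and scores each bin by the dot product between
#' the population activity vector and the loadings, normalized to the mean
#' and SD of a null distribution of dot products from `n_shuffles` cell-ID
#' shuffles of the loading vector. A bin is significantly active when the
#' activation score exceeds 2. The activity vector is the per-cell mean
#' denoised fluorescence in the bin, z-scored per cell across the session.
#'
#' @param eset an `ensemble_set`.
#' @param target a `ca_session` sharing >= 2 cells with the reference.
#' @param reg `registration_map` from reference to target ids (default:
#'   identity on shared global ids).
#' @param mask `analysis_mask` on the target (default keeps all bins).
#' @param which_ensembles indices into the eigenvector columns (default: the
#'   significant ones).
#' @param n_shuffles cell-ID shuffles (default 1000).
#' @param seed integer seed.
#' @return list of `activation_series`, one per scored ensemble: raw dot
#'   products, z `scores`, logical `significant` (z > 2), `undefined` bins
#'   (null SD zero), and the 1-s bin indices.
#' @export
activation_scores <- function(eset, target, reg = NULL,
                              mask = keep_all_mask(target),
                              which_ensembles = which(eset$significant),
                              n_shuffles = 1000, seed = 1) {
  if (is.null(reg)) {
    shared <- intersect(eset$cell_ids, target$cell_ids)
    reg <- registration_map(data.frame(id_x = shared, id_y = shared))
  }
  pairs <- reg$pairs[reg$pairs$id_x %in% eset$cell_ids &
                     reg$pairs$id_y %in% target$cell_ids, ]
  if (nrow(pairs) < 2)
    stop("activation_scores: need at least 2 shared cells")
  ba <- binned_activity(target, mask)
  A <- ba$z[, match(pairs$id_y, target$cell_ids), drop = FALSE]
  i_ref <- match(pairs$id_x, eset$cell_ids)
  lapply(which_ensembles, function(j) {
    e <- eset$vectors[i_ref, j]
    nrm <- sqrt(sum(e^2))
    if (nrm == 0) stop("activation_scores: ensemble has no loading on shared cells")
    e <- e / nrm
    dots <- as.numeric(A %*% e)
    P <- with_seed(child_seed(seed, paste0("actnull-", j)),
                   vapply(seq_len(n_shuffles), function(s) e[sample.int(length(e))],
                          numeric(length(e))))
    nulls <- A %*% P
    mu <- rowMeans(nulls)
    sdv <- row_sds(nulls)
    undef <- sdv == 0
    z <- rep(NA_real_, length(dots))
    z[!undef] <- (dots[!undef] - mu[!undef]) / sdv[!undef]
    structure(list(ensemble = j, raw = dots, scores = z,
                   significant = !is.na(z) & z > 2, undefined = undef,
                   bins_1s = ba$bins_1s, bin_width = 1,
                   context = eset$context,
                   n_shuffles = n_shuffles, seed = seed),
              class = "activation_series")
  })
}

#' @export
print.activation_series <- function(x, ...) {
  cat(sprintf("<activation_series> ensemble %d: %d/%d 1-s bins significant (z > 2), %d undefined\n",
              x$ensemble, sum(x$significant), length(x$scores),
              sum(x$undefined)))
  invisible(x)
}

#' Normalized ensemble activation rates per trial and ensemble group
#'
#' Counts significant activation bins per (trial, ensemble group), where the
#' group tags ensembles by the context they were extracted from (tagged vs
#' non-tagged), and normalizes by the total number of significant activations
#' in the session, so the tagged and non-tagged fractions sum to one over the
#' session.
#'
#' @param series list of `activation_series` for one target session.
#' @param groups character vector parallel to `series` (e.g. "tagged",
#'   "nontagged").
#' @param session the target `ca_session` (supplies the trial table).
#' @return data.frame with one row per (trial, group): counts, session-
#'   normalized `fraction`, trial context/treatment. When the session has no
#'   significant activations, fractions are NA and `total` is 0.
#' @export
activation_rate <- function(series, groups, session) {
  stopifnot(length(series) == length(groups))
  tt <- session$trial_table
  r <- session$meta$sample_rate
  total <- sum(vapply(series, function(s) sum(s$significant), 0L))
  rows <- list()
  for (g in unique(groups)) {
    for (i in seq_len(nrow(tt))) {
      cnt <- 0L
      for (k in which(groups == g)) {
        s <- series[[k]]
        sig_bins <- s$bins_1s[s$significant]
        starts <- (sig_bins - 1) * r  # 0-based 5 Hz start of each 1-s bin
        cnt <- cnt + sum(starts >= tt$start_bin[i] &
                           (starts + r) <= tt$end_bin[i])
      }
      rows[[length(rows) + 1]] <- data.frame(
        trial = i, context = tt$context_id[i], treatment = tt$treatment[i],
        group = g, count = cnt,
        fraction = if (total > 0) cnt / total else NA_real_,
        total = total)
    }
  }
  do.call(rbind, rows)
}
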