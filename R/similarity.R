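#' Average-activity population vector
#'
#' Integrates each cell's denoised trace over the kept bins, yielding one
#' average activity vector per condition (context on training days, VEH/C21
#' on probe days). The kept-bin count is recorded so integrated totals and
#' per-bin means are interconvertible.
#'
#' @param session a `ca_session`.
#' @param mask an `analysis_mask`; must keep at least one bin.
#' @param condition optional condition tag ("C1", "VEH", ...).
#' @return an `average_pv`: list with `cell_ids`, `values`, `n_bins`,
#'   `condition`.
#' @export
average_pv <- function(session, mask = build_mask(session),
                       condition = NA_character_) {
  keep <- which(mask$keep)
  if (length(keep) == 0) stop("average_pv: mask keeps no bins")
  structure(list(cell_ids = session$cell_ids,
                 values = rowSums(session$traces[, keep, drop = FALSE]),
                 n_bins = length(keep), condition = condition,
                 mouse = session$meta$mouse, day = session$meta$day),
            class = "average_pv")
}

#' @export
print.average_pv <- function(x, ...) {
  cat(sprintf("<average_pv> %d cells over %d kept bins (condition %s)\n",
              length(x$values), x$n_bins, x$condition))
  invisible(x)
}

#' Cross-session population-vector similarity on registered cells
#'
#' Restricts both average-activity vectors to cells observed in both sessions
#' (via the registration map), z-scores each restricted vector across cells
#' using the population SD convention (divide by n), and returns the per-cell
#' products c_i = z_{i,1} z_{i,2} and their mean. Under the population-SD
#' convention the self-similarity of any non-degenerate vector is exactly 1.
#'
#' @param pv_a,pv_b `average_pv` objects.
#' @param reg a `registration_map` from session A ids to session B ids
#'   (default: identity on shared global ids).
#' @return list with `per_cell` (named by session-A cell id), `mean`, and
#'   `cell_ids`.
#' @export
pv_similarity <- function(pv_a, pv_b, reg = NULL) {
  if (is.null(reg)) {
    shared <- intersect(pv_a$cell_ids, pv_b$cell_ids)
    reg <- registration_map(data.frame(id_x = shared, id_y = shared))
  }
  pairs <- reg$pairs[reg$pairs$id_x %in% pv_a$cell_ids &
                     reg$pairs$id_y %in% pv_b$cell_ids, ]
  if (nrow(pairs) < 2)
    stop("pv_similarity: need at least 2 registered shared cells")
  va <- pv_a$values[match(pairs$id_x, pv_a$cell_ids)]
  vb <- pv_b$values[match(pairs$id_y, pv_b$cell_ids)]
  sa <- pop_sd(va); sb <- pop_sd(vb)
  if (sa == 0 || sb == 0)
    stop("pv_similarity: degenerate session (zero SD across cells)")
  ci <- ((va - mean(va)) / sa) * ((vb - mean(vb)) / sb)
  names(ci) <- pairs$id_x
  list(per_cell = ci, mean = mean(ci), cell_ids = pairs$id_x)
}

#' Shuffle-normalized pairwise correlation matrix (NCM)
#'
#' Pearson correlation for every cell pair on the kept bins, normalized
#' against a null distribution obtained by circularly rotating each cell's
#' trace independently (rotation offsets uniform on [1, bins-1], drawn per
#' cell per shuffle; masked-out bins are removed before rotation). The
#' normalized value is (r - null mean) / null SD, which controls for
#' differences in average activity and transient shape while preserving each
#' trace's autocorrelation.
#'
#' @param session a `ca_session`.
#' @param mask an `analysis_mask`.
#' @param n_shuffles circular shuffles for the null (default 100).
#' @param seed integer seed.
#' @return an `ncm`: list with `cell_ids`, `values` (symmetric matrix,
#'   diagonal NA), `raw` (unnormalized correlations), and `constant_cells`
#'   (ids whose rows are undefined).
#' @export
ncm <- function(session, mask = build_mask(session), n_shuffles = 100,
                seed = 1) {
  keep <- which(mask$keep)
  X <- session$traces[, keep, drop = FALSE]
  nc <- nrow(X); nb <- ncol(X)
  if (nc < 2) stop("ncm: need at least 2 cells")
  if (nb < 10 * nc)
    warning("ncm: fewer than 10x cells kept bins; correlations will be noisy")
  const <- apply(X, 1, function(r) pop_sd(r) == 0)
  r_raw <- suppressWarnings(cor(t(X)))
  null_sum <- matrix(0, nc, nc); null_sq <- matrix(0, nc, nc)
  with_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      shifts <- sample.int(nb - 1, nc, replace = TRUE)
      Xs <- X
      for (i in seq_len(nc)) Xs[i, ] <- circular_shift(X[i, ], shifts[i])
      rs <- suppressWarnings(cor(t(Xs)))
      null_sum <- null_sum + rs
      null_sq <- null_sq + rs^2
    }
  })
  mu <- null_sum / n_shuffles
  sdv <- sqrt(pmax(null_sq / n_shuffles - mu^2, 0) *
                n_shuffles / (n_shuffles - 1))
  vals <- (r_raw - mu) / sdv
  vals[const, ] <- NA; vals[, const] <- NA
  diag(vals) <- NA
  diag(r_raw) <- NA
  structure(list(cell_ids = session$cell_ids, values = vals, raw = r_raw,
                 constant_cells = session$cell_ids[const],
                 n_shuffles = n_shuffles),
            class = "ncm")
}

#' @export
print.ncm <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<ncm> %d cells; normalized r: mean %.3f, sd %.3f (%d shuffles, %d undefined cells)\n",
              length(x$cell_ids), mean(off, na.rm = TRUE),
              sd(off, na.rm = TRUE), x$n_shuffles,
              length(x$constant_cells)))
  invisible(x)
}

#' Per-cell NCM similarity between two sessions
#'
#' For each cell detected in both sessions, takes its vector of normalized
#' correlations to every other shared cell (self entry dropped) in each
#' session and returns the Pearson correlation between the two vectors, plus
#' the mean over cells. Cells with fewer than 2 valid partners are omitted
#' and counted.
#'
#' @param ncm_a,ncm_b `ncm` objects.
#' @param reg a `registration_map` (default: identity on shared ids).
#' @return list with `per_cell` (named), `mean`, `n_omitted`.
#' @export
ncm_similarity <- function(ncm_a, ncm_b, reg = NULL) {
  if (is.null(reg)) {
    shared <- intersect(ncm_a$cell_ids, ncm_b$cell_ids)
    reg <- registration_map(data.frame(id_x = shared, id_y = shared))
  }
  pairs <- reg$pairs[reg$pairs$id_x %in% ncm_a$cell_ids &
                     reg$pairs$id_y %in% ncm_b$cell_ids, ]
  if (nrow(pairs) < 3)
    stop("ncm_similarity: need at least 3 registered shared cells")
  ia <- match(pairs$id_x, ncm_a$cell_ids)
  ib <- match(pairs$id_y, ncm_b$cell_ids)
  n <- nrow(pairs)
  out <- rep(NA_real_, n); names(out) <- pairs$id_x
  for (k in seq_len(n)) {
    va <- ncm_a$values[ia[k], ia[-k]]
    vb <- ncm_b$values[ib[k], ib[-k]]
    ok <- is.finite(va) & is.finite(vb)
    if (sum(ok) < 2) next
    out[k] <- suppressWarnings(cor(va[ok], vb[ok]))
  }
  kept <- out[is.finite(out)]
  list(per_cell = kept, mean = mean(kept), n_omitted = sum(!is.finite(out)))
}
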