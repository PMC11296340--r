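#' Detect synchronous calcium events (SCEs)
#'
#' Computes the fraction of active cells in each time bin, smooths the trace
#' with a Gaussian kernel (sigma 50 ms by default; at 5 Hz this is 0.25 bins
#' and effectively the identity — pass the 20 Hz stream and downsample
#' afterwards to smooth at acquisition rate), z-scores the smoothed trace
#' over the session, and flags bins whose z-score exceeds `z_thresh`
#' (one-sided). Event onsets are the first bins of maximal runs of
#' significant bins.
#'
#' @param binary logical cells x bins matrix (from
#'   [binarize_transients()]; >= 2 cells).
#' @param sample_rate Hz of the stream (default 5).
#' @param sigma_ms Gaussian kernel sigma in milliseconds (default 50).
#' @param z_thresh significance threshold on the z-scored trace (default 2).
#' @return an `sce_series`: `fraction_active`, smoothed `z`, logical
#'   `significant`, integer `onsets` (1-based bin indices).
#' @export
detect_sce <- function(binary, sample_rate = 5, sigma_ms = 50,
                       z_thresh = 2) {
  stopifnot(is.matrix(binary), nrow(binary) >= 2)
  frac <- colMeans(binary)
  sigma_bins <- sigma_ms / 1000 * sample_rate
  sm <- gaussian_smooth(frac, sigma_bins)
  s <- sd(sm)
  if (s == 0) {
    warning("detect_sce: constant fraction-active trace; no events")
    z <- rep(0, length(sm))
  } else {
    z <- (sm - mean(sm)) / s
  }
  sig <- z > z_thresh
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  onsets <- (ends - runs$lengths + 1L)[runs$values]
  structure(list(fraction_active = frac, z = z, significant = sig,
                 onsets = as.integer(onsets), sample_rate = sample_rate,
                 sigma_ms = sigma_ms, z_thresh = z_thresh),
            class = "sce_series")
}

#' @export
print.sce_series <- function(x, ...) {
  cat(sprintf("<sce_series> %d bins @ %g Hz: %d significant bins (z > %g), %d event onset(s)\n",
              length(x$z), x$sample_rate, sum(x$significant), x$z_thresh,
              length(x$onsets)))
  invisible(x)
}

#' Expand 1-s activation significance to the session's native bin grid
#'
#' @param act an `activation_series`.
#' @param n_bins number of native bins in the session.
#' @param sample_rate native sample rate (Hz).
#' @return logical vector of length `n_bins`.
#' @export
activation_to_bins <- function(act, n_bins, sample_rate = 5) {
  out <- rep(FALSE, n_bins)
  for (j in act$bins_1s[act$significant]) {
    idx <- ((j - 1) * sample_rate + 1):min(j * sample_rate, n_bins)
    out[idx] <- TRUE
  }
  out
}

#' Correlation between ensemble activation and synchronous events
#'
#' Smooths the binary SCE-significance trace and the binary ensemble-
#' activation trace with a Gaussian kernel (sigma 1 s), computes their
#' Pearson correlation, and compares it against the average correlation over
#' `n_shuffles` circular rotations of the activation trace.
#'
#' @param act_bins logical/numeric activation trace on the native bin grid
#'   (see [activation_to_bins()]), or an `activation_series` (expanded
#'   automatically to the SCE grid).
#' @param sce an `sce_series` (or a logical significance trace).
#' @param sample_rate Hz of the common grid (default 5).
#' @param sigma_s smoothing kernel sigma in seconds (default 1).
#' @param n_shuffles circular rotations (default 50).
#' @param seed integer seed.
#' @return list with `r`, `null` (vector of shuffle correlations),
#'   `null_mean`, and `exceeds_chance` (r > null mean).
#' @export
ensemble_sce_correlation <- function(act_bins, sce, sample_rate = 5,
                                     sigma_s = 1, n_shuffles = 50,
                                     seed = 1) {
  sce_sig <- if (inherits(sce, "sce_series")) sce$significant else sce
  if (inherits(act_bins, "activation_series"))
    act_bins <- activation_to_bins(act_bins, length(sce_sig), sample_rate)
  stopifnot(length(act_bins) == length(sce_sig))
  sigma_bins <- sigma_s * sample_rate
  a <- gaussian_smooth(as.numeric(act_bins), sigma_bins)
  b <- gaussian_smooth(as.numeric(sce_sig), sigma_bins)
  if (sd(a) == 0 || sd(b) == 0)
    stop("ensemble_sce_correlation: constant trace, correlation undefined")
  r <- cor(a, b)
  nb <- length(a)
  null <- with_seed(seed, vapply(seq_len(n_shuffles), function(s) {
    shifted <- circular_shift(as.numeric(act_bins), sample.int(nb - 1, 1))
    cor(gaussian_smooth(shifted, sigma_bins), b)
  }, 0))
  list(r = r, null = null, null_mean = mean(null),
       exceeds_chance = r > mean(null))
}

#' Peri-event average of a behavior stream
#'
#' Aligns stream segments to event onsets and averages per lag; events whose
#' window would be truncated by the session edges are dropped.
#'
#' @param stream per-bin numeric vector (e.g. speed or sniffing).
#' @param onsets 1-based bin indices of event onsets.
#' @param window_s half-window in seconds on each side of the onset.
#' @param sample_rate Hz (default 5).
#' @return data.frame with `lag_s`, `mean`, `sem`, `n_events`.
#' @export
peri_event_average <- function(stream, onsets, window_s, sample_rate = 5) {
  w <- round(window_s * sample_rate)
  nb <- length(stream)
  valid <- onsets[onsets - w >= 1 & onsets + w <= nb]
  if (length(valid) == 0)
    stop("peri_event_average: no onset lies fully inside the window margins")
  segs <- vapply(valid, function(o) stream[(o - w):(o + w)],
                 numeric(2 * w + 1))
  segs <- matrix(segs, nrow = 2 * w + 1)
  mu <- rowMeans(segs)
  sem <- if (ncol(segs) > 1) apply(segs, 1, sd) / sqrt(ncol(segs))
         else rep(0, nrow(segs))
  data.frame(lag_s = (-w:w) / sample_rate, mean = mu, sem = sem,
             n_events = length(valid))
}
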