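#' Downsample a trace matrix by block averaging
#'
#' Each output bin is the mean of `factor` consecutive input bins; a trailing
#' remainder shorter than `factor` is dropped. Used to bring 20 Hz acquisition
#' streams to the 5 Hz analysis rate.
#'
#' @param m cells x bins numeric matrix.
#' @param factor positive integer decimation factor.
#' @return cells x floor(bins/factor) matrix.
#' @export
downsample <- function(m, factor) {
  stopifnot(is.matrix(m), factor >= 1, factor == as.integer(factor))
  nb <- ncol(m)
  if (factor > nb) stop("downsample: factor exceeds number of bins")
  nout <- nb %/% factor
  if (factor == 1) return(m[, seq_len(nout), drop = FALSE])
  idx <- rep(seq_len(nout), each = factor)
  out <- t(apply(m[, seq_len(nout * factor), drop = FALSE], 1,
                 function(r) tapply(r, idx, mean)))
  dimnames(out) <- NULL
  matrix(out, nrow = nrow(m))
}

#' Binarize deconvolved transients
#'
#' A cell is active in a bin whenever its inferred transient exceeds zero.
#'
#' @param transients cells x bins non-negative matrix.
#' @return logical matrix of the same shape.
#' @export
binarize_transients <- function(transients) {
  if (any(transients < 0))
    stop("binarize_transients: negative entries violate the deconvolution contract")
  transients > 0
}

#' Per-cell transient rate
#'
#' Fraction of session time in which a transient was detected.
#'
#' @param binary logical cells x bins matrix from [binarize_transients()].
#' @return numeric vector in [0, 1], one entry per cell.
#' @export
transient_rate <- function(binary) {
  stopifnot(is.matrix(binary))
  rowMeans(binary)
}

#' Neuronal overlap between two sessions
#'
#' Fraction of session-Y cells that were also detected in session X:
#' |X intersect Y| / |Y|.
#'
#' @param cells_x,cells_y vectors of cell ids.
#' @return a fraction in [0, 1].
#' @export
neuronal_overlap <- function(cells_x, cells_y) {
  if (length(cells_y) == 0) stop("neuronal_overlap: cells_y must be non-empty")
  length(intersect(cells_x, cells_y)) / length(unique(cells_y))
}

#' Default exclusion sets for training and probe analyses
#'
#' Training analyses exclude reward-zone and outside-trial bins; probe
#' analyses additionally exclude digging and sniffing bins.
#' @return character vector of exclusion names.
#' @export
training_exclusions <- function() c("reward_zone", "outside_trial")

#' @rdname training_exclusions
#' @export
probe_exclusions <- function()
  c("reward_zone", "digging", "sniffing", "outside_trial")

#' Build the behavioral analysis mask for a session
#'
#' Marks time bins to exclude from population analyses. A bin is excluded for
#' `reward_zone` when the head position lies inside an axis-aligned
#' `box_px` x `box_px` pixel box centered on either reward well of the
#' covering trial (boundary points count as inside); for `digging`/`sniffing`
#' where those boolean streams are true; and for `outside_trial` when no trial
#' window covers the bin. `keep[t]` is true iff no exclusion applies at t.
#'
#' @param session a `ca_session`.
#' @param exclusions subset of
#'   `c("reward_zone", "digging", "sniffing", "outside_trial")`.
#' @param box_px side of the reward-zone box in pixels (default 40).
#' @return an `analysis_mask`: list with logical `keep` and a logical matrix
#'   `reasons` (bins x exclusion).
#' @export
build_mask <- function(session, exclusions = training_exclusions(),
                       box_px = 40) {
  allowed <- c("reward_zone", "digging", "sniffing", "outside_trial")
  if (!all(exclusions %in% allowed))
    stop("build_mask: unknown exclusion ", setdiff(exclusions, allowed)[1])
  nb <- n_bins(session)
  reasons <- matrix(FALSE, nb, length(allowed),
                    dimnames = list(NULL, allowed))
  tt <- session$trial_table
  in_trial <- rep(FALSE, nb)
  for (i in seq_len(nrow(tt)))
    in_trial[(tt$start_bin[i] + 1):tt$end_bin[i]] <- TRUE
  if ("outside_trial" %in% exclusions)
    reasons[, "outside_trial"] <- !in_trial
  if ("reward_zone" %in% exclusions) {
    if (is.null(session$behavior))
      stop("build_mask: exclusion 'reward_zone' requires the head_xy stream")
    xy <- session$behavior$head_xy
    half <- box_px / 2
    rz <- rep(FALSE, nb)
    for (i in seq_len(nrow(tt))) {
      idx <- (tt$start_bin[i] + 1):tt$end_bin[i]
      for (w in 1:2) {
        wx <- tt[[paste0("well", w, "_x")]][i]
        wy <- tt[[paste0("well", w, "_y")]][i]
        inside <- abs(xy[idx, 1] - wx) <= half & abs(xy[idx, 2] - wy) <= half
        rz[idx] <- rz[idx] | inside
      }
    }
    reasons[, "reward_zone"] <- rz
  }
  for (f in c("digging", "sniffing")) {
    if (f %in% exclusions) {
      if (is.null(session$behavior) || is.null(session$behavior[[f]]))
        stop(sprintf("build_mask: exclusion '%s' requires the %s stream", f, f))
      reasons[, f] <- session$behavior[[f]]
    }
  }
  keep <- rowSums(reasons) == 0
  structure(list(keep = keep, reasons = reasons, exclusions = exclusions),
            class = "analysis_mask")
}

#' A mask keeping every bin (no behavioral exclusions)
#' @param session a `ca_session`.
#' @return an `analysis_mask` with all bins kept.
#' @export
keep_all_mask <- function(session) {
  nb <- n_bins(session)
  structure(list(keep = rep(TRUE, nb),
                 reasons = matrix(FALSE, nb, 0), exclusions = character(0)),
            class = "analysis_mask")
}

#' @export
print.analysis_mask <- function(x, ...) {
  cat(sprintf("<analysis_mask> %d/%d bins kept; exclusions: %s\n",
              sum(x$keep), length(x$keep),
              if (length(x$exclusions)) paste(x$exclusions, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Restrict a mask to trials of one context or treatment
#'
#' Per-context analyses (context-wise average PVs, NCMs, ensemble
#' extraction) operate on the kept bins that fall inside trials of a single
#' context; per-treatment analyses on a probe session restrict to VEH or C21
#' trials.
#'
#' @param session a `ca_session`.
#' @param mask an `analysis_mask`.
#' @param context,treatment the trial label to keep.
#' @return the restricted `analysis_mask`.
#' @export
context_mask <- function(session, mask, context) {
  tt <- session$trial_table
  sel <- rep(FALSE, n_bins(session))
  for (i in which(tt$context_id == context))
    sel[(tt$start_bin[i] + 1):tt$end_bin[i]] <- TRUE
  mask$keep <- mask$keep & sel
  mask
}

#' @rdname context_mask
#' @export
treatment_mask <- function(session, mask, treatment) {
  tt <- session$trial_table
  sel <- rep(FALSE, n_bins(session))
  for (i in which(tt$treatment == treatment))
    sel[(tt$start_bin[i] + 1):tt$end_bin[i]] <- TRUE
  mask$keep <- mask$keep & sel
  mask
}
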