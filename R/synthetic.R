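#' Simulation configuration for the synthetic two-context experiment
#'
#' Defines the study conditions emulated by [generate_experiment()]: session
#' geometry, baseline transient statistics, noise level, day-to-day cell
#' re-detection, and the master seed. Every stochastic component derives its
#' own child generator from the master seed (see [child_seed()]), so a given
#' (config, scenario) pair reproduces its output bit-for-bit.
#'
#' @param n_cells number of globally identified cells (default 100; real
#'   sessions carry a few hundred).
#' @param n_days number of training days (default 5).
#' @param trials_per_day trials per session, alternating contexts C1/C2
#'   (default 8; must be even).
#' @param sample_rate analysis sample rate in Hz (default 5).
#' @param trial_length trial duration in whole seconds (default 20).
#' @param baseline_rate baseline transient rate, events per minute per cell
#'   (default 2).
#' @param noise_sd Gaussian noise SD on the denoised trace, in fluorescence
#'   units where a single transient has unit peak amplitude (default 0.2).
#' @param overlap_fraction fraction of cells re-detected on each day
#'   (default 1).
#' @param context_frac fraction of cells carrying an additive context offset
#'   under the divergence scenario (default 0.3, split evenly between
#'   contexts).
#' @param decay_s single-exponential calcium decay constant in seconds
#'   (default 1).
#' @param seed master integer seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_cells = 100, n_days = 5, trials_per_day = 8,
                       sample_rate = 5, trial_length = 20,
                       baseline_rate = 2, noise_sd = 0.2,
                       overlap_fraction = 1, context_frac = 0.3,
                       decay_s = 1, seed = 1) {
  cfg <- list(n_cells = n_cells, n_days = n_days,
              trials_per_day = trials_per_day, sample_rate = sample_rate,
              trial_length = trial_length, baseline_rate = baseline_rate,
              noise_sd = noise_sd, overlap_fraction = overlap_fraction,
              context_frac = context_frac, decay_s = decay_s, seed = seed)
  chk <- function(name, ok) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || !ok(v))
      stop(sprintf("sim_config: invalid value for '%s'", name), call. = FALSE)
  }
  chk("n_cells", function(v) v >= 2 && v == as.integer(v))
  chk("n_days", function(v) v >= 1 && v == as.integer(v))
  chk("trials_per_day", function(v) v >= 2 && v %% 2 == 0)
  chk("sample_rate", function(v) v > 0)
  chk("trial_length", function(v) v >= 2 && v == as.integer(v))
  chk("baseline_rate", function(v) v > 0)
  chk("noise_sd", function(v) v >= 0)
  chk("overlap_fraction", function(v) v > 0 && v <= 1)
  chk("context_frac", function(v) v >= 0 && v <= 1)
  chk("decay_s", function(v) v > 0)
  chk("seed", function(v) v == as.integer(v))
  structure(cfg, class = "sim_config")
}

INTERTRIAL_S <- 2  # gap before each trial, seconds

session_layout <- function(cfg) {
  r <- cfg$sample_rate
  L <- cfg$trial_length * r
  G <- INTERTRIAL_S * r
  starts <- G + (seq_len(cfg$trials_per_day) - 1) * (L + G)
  list(trial_bins = L, gap_bins = G, start_bin = starts,
       end_bin = starts + L, n_bins = cfg$trials_per_day * (L + G))
}

# Causal convolution of an event train with a unit-peak exponential decay
# kernel, truncated at 4 time constants so the output is exactly zero away
# from events.
exp_convolve <- function(events, decay_s, sample_rate) {
  K <- ceiling(4 * decay_s * sample_rate)
  k <- exp(-(0:K) / (decay_s * sample_rate))
  nb <- ncol(events)
  t(apply(events, 1, function(x) {
    y <- stats::filter(c(rep(0, K), x), k, method = "convolution", sides = 1)
    as.numeric(y[(K + 1):(K + nb)])
  }))
}

# 1-s windows (on the global 1-s grid) fully inside the given trial rows.
candidate_windows <- function(layout, rows, sample_rate) {
  unlist(lapply(rows, function(i) {
    first <- layout$start_bin[i] / sample_rate + 1
    last <- layout$end_bin[i] / sample_rate
    seq.int(first, last)
  }))
}

#' Generate a multi-day two-context experiment with known ground truth
#'
#' Emulates the statistical structure the population analyses assume: two
#' contexts visited in alternating trials on each training day, per-cell
#' Poisson transients convolved with an exponential decay kernel (the
#' noiseless convolution is the deconvolved-transient channel; Gaussian noise
#' is added for the denoised trace), sparse context coding via additive mean
#' offsets, planted coactive ensembles firing in discrete 1-s windows,
#' planted population-synchrony events, and day-to-day partial cell
#' re-detection with exact registration maps.
#'
#' Scenarios:
#' \describe{
#'   \item{null}{no context signal: the separation schedule is identically
#'     zero and ensembles activate in both contexts at the base rate.}
#'   \item{divergence}{additive context-specific offsets grow across days
#'     following `separation_schedule` (default: linear ramp from 0 to
#'     3 x `noise_sd`).}
#'   \item{probe_reinstatement}{training days as in divergence, plus a final
#'     probe session with alternating VEH/C21 trials in which the
#'     tagged-context ensemble activates preferentially in C21 trials.}
#' }
#'
#' @param cfg a [sim_config()].
#' @param scenario one of "null", "divergence", "probe_reinstatement".
#' @param separation_schedule optional non-negative, per-day context offset
#'   (fluorescence units); must be non-decreasing for divergence-type
#'   scenarios.
#' @param n_ensembles planted ensembles (default 2: one per context; the C1
#'   ensemble is the "tagged" one).
#' @param ensemble_size member cells per ensemble (default 15).
#' @param ensemble_amplitude event amplitude added to each member within an
#'   activation window, default `3 * cfg$noise_sd`.
#' @param ensemble_event_frac fraction of a context's 1-s windows carrying an
#'   ensemble activation (default 0.05).
#' @param n_sce planted synchronous events per session (default 6).
#' @param sce_frac fraction of all cells co-active in a planted synchronous
#'   event (default 0.6).
#' @param ensembles_in_sce if TRUE, ensemble activation windows are placed
#'   exactly at the planted synchronous-event windows (used to emulate
#'   SCE-locked ensemble reactivation).
#' @param probe_fracs activation-window fractions for the probe session:
#'   named list with `tagged_c21`, `tagged_veh`, `nontagged` (defaults 0.10,
#'   0.02, 0.04).
#' @param behavior if TRUE (default) behavior streams are attached via
#'   [generate_behavior()].
#' @return list with `sessions` (list of `ca_session`), `registration`
#'   (maps between consecutive sessions), and `truth` (a `ground_truth`).
#' @export
generate_experiment <- function(cfg,
                                scenario = c("null", "divergence",
                                             "probe_reinstatement"),
                                separation_schedule = NULL,
                                n_ensembles = 2, ensemble_size = 15,
                                ensemble_amplitude = 3 * cfg$noise_sd,
                                ensemble_event_frac = 0.05,
                                n_sce = 6, sce_frac = 0.6,
                                ensembles_in_sce = FALSE,
                                probe_fracs = list(tagged_c21 = 0.10,
                                                   tagged_veh = 0.02,
                                                   nontagged = 0.04),
                                behavior = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  scenario <- match.arg(scenario)
  r <- cfg$sample_rate
  lay <- session_layout(cfg)
  n_days <- cfg$n_days
  has_probe <- scenario == "probe_reinstatement"

  if (is.null(separation_schedule)) {
    separation_schedule <- if (scenario == "null") rep(0, n_days)
      else seq(0, 3 * cfg$noise_sd, length.out = n_days)
  }
  if (length(separation_schedule) != n_days ||
      any(separation_schedule < 0))
    stop("generate_experiment: invalid value for 'separation_schedule'")
  if (scenario != "null" && is.unsorted(separation_schedule))
    stop("generate_experiment: 'separation_schedule' must be non-decreasing")

  # cell roles
  coding <- with_seed(child_seed(cfg$seed, "coding"), {
    n_code <- round(cfg$context_frac * cfg$n_cells)
    ids <- sample.int(cfg$n_cells, n_code)
    split(ids, rep(c("C1", "C2"), length.out = n_code))
  })
  ens <- with_seed(child_seed(cfg$seed, "ensembles"), {
    pool <- setdiff(seq_len(cfg$n_cells), unlist(coding))
    if (n_ensembles > 0) {
      # small simulations cannot host full-size ensembles; scale down and
      # drop them entirely below 2 members
      ensemble_size <- min(ensemble_size, length(pool) %/% n_ensembles)
      if (ensemble_size < 2) n_ensembles <- 0
    }
    lapply(seq_len(n_ensembles), function(e) {
      members <- sort(sample(pool, ensemble_size))
      pool <<- setdiff(pool, members)
      list(members = members,
           context = c("C1", "C2")[((e - 1) %% 2) + 1],
           amplitude = ensemble_amplitude)
    })
  })

  n_ensembles <- length(ens)

  trial_table_for <- function(kind) {
    n_tr <- cfg$trials_per_day
    data.frame(
      start_bin = lay$start_bin, end_bin = lay$end_bin,
      context_id = if (kind == "probe") rep("novel", n_tr)
                   else rep(c("C1", "C2"), length.out = n_tr),
      treatment = if (kind == "probe") rep(c("VEH", "C21"),
                                           length.out = n_tr)
                  else rep("none", n_tr),
      well1_x = 100, well1_y = 100, well2_x = 300, well2_y = 300,
      stringsAsFactors = FALSE)
  }

  kinds <- c(rep("training", n_days), if (has_probe) "probe")
  n_sessions <- length(kinds)
  detected <- with_seed(child_seed(cfg$seed, "registration"), {
    lapply(seq_len(n_sessions), function(d) {
      n_det <- round(cfg$overlap_fraction * cfg$n_cells)
      sort(sample.int(cfg$n_cells, n_det))
    })
  })

  sessions <- vector("list", n_sessions)
  ens_windows <- lapply(seq_len(n_ensembles),
                        function(e) vector("list", n_sessions))
  sce_windows <- vector("list", n_sessions)

  for (d in seq_len(n_sessions)) {
    kind <- kinds[d]
    tt <- trial_table_for(kind)
    nb <- lay$n_bins

    events <- with_seed(child_seed(cfg$seed, paste0("events-", d)), {
      p <- cfg$baseline_rate / 60 / r
      matrix(rbinom(cfg$n_cells * nb, 1, p), cfg$n_cells, nb) * 1.0
    })

    # planted synchronous events at 1-s window starts inside trials
    sw <- with_seed(child_seed(cfg$seed, paste0("sce-", d)), {
      cand <- candidate_windows(lay, seq_len(nrow(tt)), r)
      # keep clear of session edges for peri-event analyses
      cand <- cand[cand > 6 & cand < (nb / r - 6)]
      sort(sample(cand, min(n_sce, length(cand))))
    })
    sce_windows[[d]] <- sw
    with_seed(child_seed(cfg$seed, paste0("sce-cells-", d)), {
      for (w in sw) {
        cells <- sample.int(cfg$n_cells, round(sce_frac * cfg$n_cells))
        b <- (w - 1) * r + 1
        events[cells, b] <- events[cells, b] + 1.0
      }
    })

    # planted ensemble activations
    for (e in seq_len(n_ensembles)) {
      ctx <- ens[[e]]$context
      tagged <- ctx == "C1"
      wins <- with_seed(child_seed(cfg$seed, sprintf("ens-%d-%d", e, d)), {
        if (kind == "probe") {
          pick <- function(rows, frac) {
            cand <- candidate_windows(lay, rows, r)
            sort(sample(cand, max(1, round(frac * length(cand)))))
          }
          veh <- which(tt$treatment == "VEH")
          c21 <- which(tt$treatment == "C21")
          if (tagged)
            c(pick(c21, probe_fracs$tagged_c21),
              pick(veh, probe_fracs$tagged_veh))
          else c(pick(c21, probe_fracs$nontagged),
                 pick(veh, probe_fracs$nontagged))
        } else if (ensembles_in_sce && tagged) {
          sw
        } else {
          rows <- if (scenario == "null") seq_len(nrow(tt))
                  else which(tt$context_id == ctx)
          cand <- candidate_windows(lay, rows, r)
          cand <- setdiff(cand, sw)
          sort(sample(cand, max(1, round(ensemble_event_frac * length(cand)))))
        }
      })
      ens_windows[[e]][[d]] <- wins
      b <- (wins - 1) * r + 1
      events[ens[[e]]$members, b] <-
        events[ens[[e]]$members, b] + ens[[e]]$amplitude
    }

    transients <- exp_convolve(events, cfg$decay_s, r)
    traces <- transients +
      with_seed(child_seed(cfg$seed, paste0("noise-", d)),
                matrix(rnorm(cfg$n_cells * nb, 0, cfg$noise_sd),
                       cfg$n_cells, nb))

    # additive context offsets for coding cells (training days only)
    if (kind == "training" && separation_schedule[d] > 0) {
      for (ctx in c("C1", "C2")) {
        rows <- which(tt$context_id == ctx)
        idx <- unlist(lapply(rows, function(i)
          (tt$start_bin[i] + 1):tt$end_bin[i]))
        traces[coding[[ctx]], idx] <-
          traces[coding[[ctx]], idx] + separation_schedule[d]
      }
    }

    det <- detected[[d]]
    s <- ca_session(traces[det, , drop = FALSE],
                    transients[det, , drop = FALSE],
                    cell_ids = det, trial_table = tt,
                    meta = list(day = d, kind = kind, sample_rate = r,
                                mouse = "sim1"))
    if (behavior)
      s <- generate_behavior(s, cfg,
                             seed = child_seed(cfg$seed,
                                               paste0("behavior-", d)))
    sessions[[d]] <- s
  }

  registration <- lapply(seq_len(max(n_sessions - 1, 0)), function(d)
    register_by_id(sessions[[d]], sessions[[d + 1]]))

  truth <- structure(list(
    scenario = scenario,
    context_separation_per_day = separation_schedule,
    coding_cells = coding,
    ensembles = lapply(seq_len(n_ensembles), function(e) {
      x <- ens[[e]]
      x$tagged <- x$context == "C1"
      x$windows_1s <- ens_windows[[e]]
      # windows where the planted bump is present in the trace: the event
      # window plus the calcium decay tail (one window per decay constant)
      x$influence_windows_1s <- lapply(ens_windows[[e]], function(w)
        sort(unique(c(w, outer(w, seq_len(ceiling(cfg$decay_s)), "+")))))
      x$activation_bins <- lapply(ens_windows[[e]], function(w)
        as.integer(sort(outer((w - 1) * r, seq_len(r), "+"))))
      x
    }),
    sce_windows_1s = sce_windows,
    sce_bins = lapply(sce_windows, function(w) as.integer((w - 1) * r + 1)),
    registration_truth = detected,
    treatment_labels = if (has_probe)
      trial_table_for("probe")$treatment else NULL),
    class = "ground_truth")

  list(sessions = sessions, registration = registration, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> scenario '%s': %d sessions, %d ensembles, schedule %s\n",
              x$scenario, length(x$registration_truth), length(x$ensembles),
              paste(signif(x$context_separation_per_day, 3), collapse = "/")))
  invisible(x)
}

#' Serialize / load ground truth as JSON
#' @param truth a `ground_truth`.
#' @param path output file.
#' @return the path (write) or a `ground_truth` (read).
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "ground_truth")
}

#' Populate behavior streams for a session
#'
#' Generates a 5 Hz head-position track that, by default, routes through both
#' reward wells once per trial (piecewise-linear waypoint paths with jitter),
#' derives speed from successive positions, and draws sparse digging and
#' sniffing bouts. Options emulate specific behavioral regimes:
#' `stationary` parks the animal (speed identically zero); `zone_entries =
#' FALSE` keeps the path outside both reward-zone boxes; `sce_locked_slowing`
#' scales down movement for 2 s after each supplied synchrony bin, emulating
#' event-locked quiescence (zone entries are then no longer guaranteed).
#'
#' @param session a `ca_session`.
#' @param cfg the [sim_config()] that produced it.
#' @param stationary logical.
#' @param zone_entries logical; guarantee at least one entry per well per
#'   trial (default TRUE).
#' @param sce_locked_slowing logical.
#' @param sce_bins 5 Hz bin indices of synchrony events (required when
#'   `sce_locked_slowing`).
#' @param box_px reward-zone box side used for avoidance when
#'   `zone_entries = FALSE`.
#' @param seed integer seed (default derived from `cfg$seed` and the day).
#' @return the session with `behavior` populated.
#' @export
generate_behavior <- function(session, cfg, stationary = FALSE,
                              zone_entries = TRUE,
                              sce_locked_slowing = FALSE, sce_bins = NULL,
                              box_px = 40,
                              seed = child_seed(cfg$seed,
                                                paste0("behavior-",
                                                       session$meta$day))) {
  tt <- session$trial_table
  if (nrow(tt) == 0) stop("generate_behavior: trial table required")
  nb <- n_bins(session)
  r <- session$meta$sample_rate
  wells <- cbind(c(tt$well1_x[1], tt$well2_x[1]),
                 c(tt$well1_y[1], tt$well2_y[1]))
  if (abs(wells[1, 1] - wells[2, 1]) <= box_px &&
      abs(wells[1, 2] - wells[2, 2]) <= box_px)
    stop("generate_behavior: reward-zone boxes overlap")
  arena <- c(20, 380)

  b <- with_seed(seed, {
    if (stationary) {
      xy <- matrix(rep(c(200, 200), each = nb), nb, 2)
    } else {
      xy <- matrix(NA_real_, nb, 2)
      # when zone entries are disabled, waypoints are confined to the
      # vertical strip between the two well boxes, which is convex and
      # disjoint from both boxes, so no path segment can cross a zone
      rand_pt <- function() {
        if (zone_entries) runif(2, arena[1], arena[2])
        else c(runif(1, 150, 250), runif(1, arena[1], arena[2]))
      }
      pos <- rand_pt()
      last_end <- 0L
      for (i in seq_len(nrow(tt))) {
        gap <- (last_end + 1):tt$start_bin[i]
        if (tt$start_bin[i] >= last_end + 1)
          xy[gap, ] <- matrix(rep(pos, each = length(gap)), ncol = 2)
        idx <- (tt$start_bin[i] + 1):tt$end_bin[i]
        wp <- if (zone_entries) rbind(pos, wells[1, ], wells[2, ], rand_pt())
              else rbind(pos, rand_pt(), rand_pt(), rand_pt())
        seg_len <- sqrt(rowSums(diff(wp)^2))
        alloc <- pmax(2, round(length(idx) * seg_len / sum(seg_len)))
        while (sum(alloc) > length(idx)) alloc[which.max(alloc)] <-
          alloc[which.max(alloc)] - 1
        while (sum(alloc) < length(idx)) alloc[which.max(seg_len)] <-
          alloc[which.max(seg_len)] + 1
        path <- do.call(rbind, lapply(1:3, function(k)
          cbind(seq(wp[k, 1], wp[k + 1, 1], length.out = alloc[k]),
                seq(wp[k, 2], wp[k + 1, 2], length.out = alloc[k]))))
        xy[idx, ] <- path[seq_along(idx), ]
        pos <- xy[idx[length(idx)], ]
        last_end <- tt$end_bin[i]
      }
      if (last_end < nb)
        xy[(last_end + 1):nb, ] <- matrix(rep(pos, each = nb - last_end),
                                          ncol = 2)
      xy <- xy + matrix(rnorm(2 * nb, 0, 0.5), nb, 2)  # tracking jitter
      if (sce_locked_slowing) {
        if (is.null(sce_bins))
          stop("generate_behavior: sce_bins required for sce_locked_slowing")
        v <- rbind(c(0, 0), diff(xy))
        slow <- rep(FALSE, nb)
        for (s0 in sce_bins) {
          w <- s0:min(nb, s0 + 2 * r)
          slow[w] <- TRUE
        }
        v[slow, ] <- v[slow, ] * 0.15
        xy <- matrix(rep(xy[1, ], each = nb), nb, 2) +
          apply(v, 2, cumsum)
      }
    }
    speed <- c(0, sqrt(rowSums(diff(xy)^2)) * r)
    bout_stream <- function(rate_per_trial, len_s) {
      z <- rep(FALSE, nb)
      for (i in seq_len(nrow(tt))) {
        n_bouts <- rpois(1, rate_per_trial)
        if (n_bouts == 0) next
        idx <- (tt$start_bin[i] + 1):tt$end_bin[i]
        for (k in seq_len(n_bouts)) {
          st <- sample(idx, 1)
          z[st:min(max(idx), st + round(len_s * r))] <- TRUE
        }
      }
      z
    }
    list(head_xy = xy, speed = speed,
         digging = bout_stream(0.5, 1.5), sniffing = bout_stream(1, 1))
  })
  session$behavior <- b
  validate_session(session)
  session
}
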