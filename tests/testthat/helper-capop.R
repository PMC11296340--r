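# Small in-code fixtures shared across the suite.

make_trial_table <- function(n_trials = 4, len = 50, gap = 10,
                             contexts = rep(c("C1", "C2"),
                                            length.out = n_trials),
                             treatment = rep("none", n_trials)) {
  starts <- gap + (seq_len(n_trials) - 1) * (len + gap)
  data.frame(start_bin = starts, end_bin = starts + len,
             context_id = contexts, treatment = treatment,
             well1_x = 100, well1_y = 100, well2_x = 300, well2_y = 300,
             stringsAsFactors = FALSE)
}

# a minimal valid session around a given trace matrix
make_session <- function(traces, transients = NULL, trial_table = NULL,
                         behavior = NULL, meta = list()) {
  nb <- ncol(traces)
  if (is.null(transients)) transients <- matrix(0, nrow(traces), nb)
  if (is.null(trial_table))
    trial_table <- data.frame(start_bin = 0, end_bin = nb,
                              context_id = "C1", treatment = "none",
                              well1_x = 100, well1_y = 100,
                              well2_x = 300, well2_y = 300)
  ca_session(traces, transients, seq_len(nrow(traces)), trial_table,
             behavior = behavior, meta = meta)
}

# straight-line head track visiting given points at given bins
track_behavior <- function(nb, xy = cbind(rep(200, nb), rep(200, nb))) {
  list(head_xy = xy, speed = rep(0, nb), digging = rep(FALSE, nb),
       sniffing = rep(FALSE, nb))
}

# independent O(n^2) oracle for the PV distance ratio: explicit loop over
# ordered pairs, mean(between) / mean(within)
brute_force_ratio <- function(v, labels) {
  n <- nrow(v)
  btw <- c(); wth <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- 1 - sum(v[i, ] * v[j, ]) /
      (sqrt(sum(v[i, ]^2)) * sqrt(sum(v[j, ]^2)))
    if (labels[i] == labels[j]) wth <- c(wth, d) else btw <- c(btw, d)
  }
  mean(btw) / mean(wth)
}

# mean silhouette for a 2-cluster labelling (used to verify embeddings)
silhouette2 <- function(x, labels) {
  d <- as.matrix(dist(x))
  mean(vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(x)) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, 0))
}
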