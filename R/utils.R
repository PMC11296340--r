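#' @importFrom stats approx cor prcomp rnorm rpois runif sd quantile rbinom
#' @importFrom utils packageVersion head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic component of the pipeline draws from its own child
#' generator so that, e.g., regenerating behavior does not perturb the trace
#' noise. The child seed is a deterministic 31-bit hash of the master seed and
#' a purpose string.
#'
#' @param seed master seed (integer).
#' @param purpose character tag naming the consumer (e.g. "traces-day3").
#' @return an integer in [0, 2^31 - 2] usable with [set.seed()].
#' @export
child_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(purpose)) {
    h <- (h * 131 + k) %% m
  }
  as.integer(h)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Circularly rotate a vector by `shift` positions (wraparound).
circular_shift <- function(x, shift) {
  n <- length(x)
  shift <- shift %% n
  if (shift == 0) return(x)
  c(x[(n - shift + 1):n], x[1:(n - shift)])
}

#' Gaussian smoothing of a time series
#'
#' Convolves with a discrete Gaussian kernel (truncated at 4 standard
#' deviations, normalized to sum to one) using reflected boundaries, so the
#' mean of the trace is conserved away from the edges.
#'
#' @param x numeric vector.
#' @param sigma_bins kernel standard deviation in bins; values below ~0.2 bins
#'   make the kernel a single bin, i.e. the identity.
#' @return smoothed numeric vector of the same length.
#' @export
gaussian_smooth <- function(x, sigma_bins) {
  stopifnot(is.numeric(x), sigma_bins >= 0)
  half <- ceiling(4 * sigma_bins)
  if (half < 1) return(x)
  k <- exp(-((-half:half)^2) / (2 * sigma_bins^2))
  k <- k / sum(k)
  n <- length(x)
  pad <- min(half, n - 1)
  xp <- c(x[(pad + 1):2][seq_len(pad)], x, x[(n - 1):(n - pad)][seq_len(pad)])
  # padded reflection; convolve and cut back
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(pad + 1):(pad + n)])
}

# Population-convention SD (divide by n, not n - 1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Row-wise sample SDs of a matrix (null-distribution summaries).
row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2), 0) / (n - 1))
}

# Short deterministic hex hash of an R object (provenance columns).
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  m <- 2147483647
  h <- 7
  for (k in utf8ToInt(s)) h <- (h * 131 + k) %% m
  sprintf("%08x", as.integer(h))
}

stop_field <- function(field, msg) {
  stop(sprintf("validation error in '%s': %s", field, msg), call. = FALSE)
}
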