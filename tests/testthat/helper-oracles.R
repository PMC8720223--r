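# Independent oracles used across test files.  These deliberately
# re-derive the quantities from first principles (dense double loops,
# base-R hulls, literal counting) and never call the implementation
# paths they check.

# Literal dense transcription of the kernel-smoothing definition:
# full T x T weight matrix, no truncation, no FFT.
oracle_smooth <- function(values, times, sigma) {
  W <- exp(-outer(times, times, "-")^2 / (2 * sigma^2))
  as.vector(W %*% values) / rowSums(W)
}

oracle_j <- function(values, times, sigma) {
  sqrt(mean((oracle_smooth(values, times, sigma) - values)^2))
}

# Convex-hull area through grDevices::chull (Graham-scan based),
# independent of the package's gift-wrapping march.
oracle_hull_area <- function(x, y) {
  h <- grDevices::chull(x, y)
  if (length(h) < 3L) return(0)
  xs <- x[h]; ys <- y[h]
  j <- c(2:length(xs), 1L)
  abs(sum(xs * ys[j] - xs[j] * ys)) / 2
}

# Simple uniform-grid path helpers.
make_path <- function(values, step = 0.01, frontal = NULL,
                      side = "paretic") {
  hand_path((seq_along(values) - 1L) * step, values, frontal = frontal,
            side = side)
}

# Draws from the generative bounded tanh score model for recovery
# studies: Z ~ N(0,1), S = a tanh(Z beta + beta0 + sigma1 u) + b +
# sigma2 v.
gen_tanh_data <- function(n, beta, beta0, a, b, sigma1, sigma2, seed) {
  set.seed(seed)
  p <- length(beta)
  Z <- matrix(stats::rnorm(n * p), n, p)
  S <- a * tanh(as.vector(Z %*% beta) + beta0 +
                  sigma1 * stats::rnorm(n)) + b +
    sigma2 * stats::rnorm(n)
  list(Z = Z, S = S)
}

# One small simulated cohort shared across test files (built lazily,
# once per test run).  Short sessions keep the suite fast while
# retaining ~18 target events after trimming.
cohort_cache <- new.env(parent = emptyenv())
test_cohort <- function() {
  if (is.null(cohort_cache$cohort))
    cohort_cache$cohort <- simulate_cohort(simulation_config(
      n_patients = 14, session_duration = 420, seed = 301))
  cohort_cache$cohort
}
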