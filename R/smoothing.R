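#' Gaussian-kernel trajectory smoothing
#'
#' Smooths a sampled trajectory `f(t_i)` with a normalized Gaussian
#' kernel of timescale `sigma`:
#' \deqn{f_\sigma(t_i) = \frac{\sum_j f(t_j)\,
#'   e^{-(t_i-t_j)^2/2\sigma^2}}{\sum_j e^{-(t_i-t_j)^2/2\sigma^2}}}
#' The sum runs over *all* samples (full pairwise weighting, no
#' truncation).  Two evaluation paths give the same sums: on a uniform
#' time grid the kernel sums are computed as FFT convolutions; on
#' non-uniform grids a blocked dense evaluation is used.  Both drop only
#' pairs whose weight underflows to exactly zero in double precision
#' (beyond 39 sigma), so the result equals the full double sum.
#'
#' @param values Numeric series `f(t_i)`.
#' @param times Timestamps in seconds, strictly increasing.
#' @param sigma Smoothing timescale in seconds, > 0.
#'
#' @return Numeric vector `f_sigma(t_i)`, same length as `values`.
#' @export
gaussian_smooth <- function(values, times, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("'sigma' must be a positive number", call. = FALSE)
  if (length(values) != length(times))
    stop("'values' and 'times' must have the same length", call. = FALSE)
  if (!all(is.finite(values)) || !all(is.finite(times)))
    stop("'values' and 'times' must be finite", call. = FALSE)
  n <- length(values)
  if (n == 1L) return(values)
  d <- diff(times)
  if (any(d <= 0)) stop("'times' must be strictly increasing", call. = FALSE)
  delta <- mean(d)
  if (max(abs(d - delta)) <= 1e-6 * delta && n > 64L) {
    smooth_uniform_fft(values, delta, sigma)
  } else {
    smooth_dense(values, times, sigma)
  }
}

# Kernel weights exp(-(d/sigma)^2/2) underflow to exactly 0 in double
# precision once (d/sigma)^2/2 > ~745; a 39-sigma cutoff therefore
# reproduces the full pairwise sum bit-for-bit up to summation order.
KERNEL_CUTOFF_SIGMAS <- 39

smooth_uniform_fft <- function(values, delta, sigma) {
  n <- length(values)
  m <- min(n - 1L, ceiling(KERNEL_CUTOFF_SIGMAS * sigma / delta))
  kern <- exp(-((-m:m) * delta)^2 / (2 * sigma^2))
  len <- stats::nextn(n + 2L * m, c(2, 3, 5))
  fk <- stats::fft(c(kern, rep(0, len - length(kern))))
  circ <- function(x) {
    fx <- stats::fft(c(x, rep(0, len - n)))
    Re(stats::fft(fx * fk, inverse = TRUE))[(m + 1):(m + n)] / len
  }
  circ(values) / circ(rep(1, n))
}

smooth_dense <- function(values, times, sigma) {
  n <- length(values)
  out <- numeric(n)
  cut <- KERNEL_CUTOFF_SIGMAS * sigma
  block <- max(16L, min(n, floor(4e6 / n)))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + block - 1L)
    tb <- times[i:j]
    lo <- findInterval(tb[1] - cut, times) # last index with time <= lower bound
    lo <- max(1L, lo)
    hi <- findInterval(tb[length(tb)] + cut, times)
    hi <- min(n, max(hi, lo))
    w <- exp(-outer(tb, times[lo:hi], "-")^2 / (2 * sigma^2))
    out[i:j] <- as.vector(w %*% values[lo:hi]) / rowSums(w)
    i <- j + 1L
  }
  out
}

#' Timescale-resolved displacement statistic J(sigma)
#'
#' The root-mean-square difference between a trajectory and its
#' Gaussian-smoothed version at timescale `sigma`:
#' \deqn{J(\sigma) = \sqrt{\frac{1}{T}\sum_i
#'   \left[f_\sigma(t_i) - f(t_i)\right]^2}}
#' Evaluated at a small `sigma` (comparable to the sampling step) it
#' quantifies fast, jittery movement components ("Smoothness"); at a
#' `sigma` comparable to the inter-target interval of the task it
#' quantifies the displacement spent on goal-directed reaches (the
#' Total Goal-Directed Movement, TGDM).
#'
#' @inheritParams gaussian_smooth
#' @return J(sigma) in the units of `values` (metres for positions).
#' @export
j_statistic <- function(values, times, sigma) {
  fs <- gaussian_smooth(values, times, sigma)
  sqrt(mean((fs - values)^2))
}

#' Default log-spaced sigma grid for correlation sweeps
#'
#' @param n Number of grid points.
#' @param range Two-element range in seconds.
#' @return Increasing numeric vector of timescales (s).
#' @export
default_sigma_grid <- function(n = 60, range = c(0.005, 50)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Sweep J(sigma) across sessions and locate its correlation peaks
#'
#' Computes `J(sigma)` for every session on a grid of timescales, then
#' the Pearson correlation between `J(sigma)` and a clinical score
#' across sessions at each timescale.  The correlation curve typically
#' shows two peaks: a high-frequency peak near the data time resolution
#' (defining the Smoothness timescale) and a low-frequency peak near the
#' task's inter-target timescale (defining the TGDM timescale).
#'
#' @param paths List of [hand_path] objects (one session each),
#'   already trimmed.
#' @param scores Numeric clinical scores, one per session.
#' @param axis `"lateral"` or `"frontal"`.
#' @param grid Increasing positive timescale grid in seconds.
#' @param split Timescale (s) separating the high-frequency from the
#'   low-frequency peak search ranges (default 0.5 s).
#'
#' @return A list of class `sigma_correlation_curve` with elements
#'   `sigmas`, `j_values` (sessions x sigmas matrix), `r_values`,
#'   `peak_high_sigma` (high-frequency peak, small sigma) and
#'   `peak_low_sigma` (low-frequency peak, large sigma).
#' @export
sigma_sweep <- function(paths, scores, axis = c("lateral", "frontal"),
                        grid = default_sigma_grid(), split = 0.5) {
  axis <- match.arg(axis)
  if (length(paths) < 3L || length(scores) != length(paths))
    stop("need at least 3 sessions with matching scores", call. = FALSE)
  if (any(grid <= 0) || any(diff(grid) <= 0))
    stop("'grid' must be positive and increasing", call. = FALSE)
  if (stats::sd(scores) == 0)
    stop("correlation undefined: scores are constant", call. = FALSE)
  J <- vapply(paths, function(p) {
    v <- path_axis(p, axis)
    vapply(grid, function(s) j_statistic(v, p$times, s), numeric(1))
  }, numeric(length(grid)))
  J <- t(matrix(J, nrow = length(grid))) # sessions x sigmas
  r <- apply(J, 2L, function(col) {
    if (stats::sd(col) == 0) 0 else stats::cor(col, scores)
  })
  lo_set <- which(grid <= split)
  hi_set <- which(grid > split)
  if (!length(lo_set)) lo_set <- seq_along(grid)
  if (!length(hi_set)) hi_set <- seq_along(grid)
  structure(list(sigmas = grid, j_values = J, r_values = r,
                 peak_high_sigma = grid[lo_set[which.max(r[lo_set])]],
                 peak_low_sigma = grid[hi_set[which.max(r[hi_set])]],
                 axis = axis, split = split),
            class = "sigma_correlation_curve")
}

#' @export
print.sigma_correlation_curve <- function(x, ...) {
  cat(sprintf(paste0("<sigma_correlation_curve> %d sessions x %d sigmas",
                     " (%s axis)\n  high-frequency peak %.3g s,",
                     " low-frequency peak %.3g s\n"),
              nrow(x$j_values), length(x$sigmas), x$axis,
              x$peak_high_sigma, x$peak_low_sigma))
  invisible(x)
}

#' Default TGDM timescales per clinical scale
#'
#' Low-frequency correlation-peak timescales used by default when
#' extracting the TGDM for a given target scale: 8.8 s for FM-UE,
#' 5.9 s for CAHAI and 17 s for BI.
#'
#' @return Named numeric vector of timescales (s).
#' @export
tgdm_sigma_defaults <- function() {
  c(fm_ue = 8.8, cahai = 5.9, bi = 17)
}

#' Movement smoothness descriptor (mm)
#'
#' `J(sigma)` evaluated at a high-frequency timescale (default 0.01 s,
#' the data time resolution), reported in millimetres.  Larger values
#' indicate more high-frequency, jittery movement.
#'
#' @param path A trimmed [hand_path].
#' @param sigma_high Timescale in seconds (default 0.01).
#' @param axis Trajectory axis to use.
#' @return Smoothness in mm.
#' @export
extract_smoothness <- function(path, sigma_high = 0.01,
                               axis = c("lateral", "frontal")) {
  axis <- match.arg(axis)
  1000 * j_statistic(path_axis(path, axis), path$times, sigma_high)
}

#' Total Goal-Directed Movement (m)
#'
#' `J(sigma)` evaluated at a low-frequency timescale matched to the
#' task's inter-target interval; captures the displacement range of
#' goal-directed reaches.  Defaults to the FM-UE peak timescale of
#' 8.8 s; see [tgdm_sigma_defaults()] for the other scales.  For tasks
#' using the full plane, compute it per axis (`"lateral"` and
#' `"frontal"`).
#'
#' @param path A trimmed [hand_path].
#' @param axis Trajectory axis to use.
#' @param sigma_low Timescale in seconds (default 8.8).
#' @return TGDM in metres.
#' @export
extract_tgdm <- function(path, axis = c("lateral", "frontal"),
                         sigma_low = 8.8) {
  axis <- match.arg(axis)
  j_statistic(path_axis(path, axis), path$times, sigma_low)
}
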