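#' Parameters of the bounded double-noise score model
#'
#' The generative model for a clinical score `S` given normalized
#' covariates `Z` is
#' \deqn{S = a\,\tanh(\beta \cdot Z + \beta_0 + \sigma_1 u) + b +
#'   \sigma_2 v, \quad a = (B-A)/2,\ b = (B+A)/2,}
#' with independent standard-normal noise `u` inside the saturating
#' link ("covariate noise") and `v` outside it ("score noise").  The
#' tanh saturation keeps the noise-averaged score inside the fitted
#' range `[A, B]`, mirroring the bounded nature of clinical scales.
#' The sign ambiguity of tanh is removed by requiring `B >= A`
#' (i.e. `a >= 0`).
#'
#' @param beta Numeric vector of association parameters (per
#'   normalized covariate).
#' @param beta0 Scalar offset.
#' @param A,B Score-range offsets with `B >= A`.
#' @param sigma1 Covariate-noise strength, >= 0.
#' @param sigma2 Score-noise strength, >= 0.
#'
#' @return Object of class `noise_model_params` with derived `a`, `b`.
#' @export
noise_model_params <- function(beta, beta0, A, B, sigma1 = 0, sigma2 = 0) {
  beta <- as.numeric(beta)
  stopifnot(is.finite(beta0), is.finite(A), is.finite(B),
            all(is.finite(beta)), sigma1 >= 0, sigma2 >= 0)
  if (B < A) stop("'B' must be >= 'A'", call. = FALSE)
  structure(list(beta = beta, beta0 = beta0, A = A, B = B,
                 sigma1 = sigma1, sigma2 = sigma2,
                 a = (B - A) / 2, b = (B + A) / 2),
            class = "noise_model_params")
}

#' @rdname noise_model_params
#' @param a,b Alternative range parameterization: half-range `a >= 0`
#'   and midpoint `b` (so `A = b - a`, `B = b + a`).
#' @export
noise_model_params_ab <- function(beta, beta0, a, b,
                                  sigma1 = 0, sigma2 = 0) {
  if (a < 0) stop("'a' must be >= 0", call. = FALSE)
  noise_model_params(beta, beta0, A = b - a, B = b + a,
                     sigma1 = sigma1, sigma2 = sigma2)
}

#' @export
print.noise_model_params <- function(x, ...) {
  cat(sprintf(paste0("<noise_model_params> p=%d, a=%.4g, b=%.4g, ",
                     "sigma1=%.4g, sigma2=%.4g\n"),
              length(x$beta), x$a, x$b, x$sigma1, x$sigma2))
  invisible(x)
}

#' Regularisation prior configuration
#'
#' Improper MAP prior: a ridge penalty `d/2 |beta|^2` on the
#' association parameters and weight `exp(-q/sigma)` on each noise
#' strength with `q` a very small constant (of the order of the
#' numerical accuracy), which bounds the regularised objective from
#' below as a noise strength approaches zero.
#'
#' @param d Ridge strength on `beta` (>= 0); default 1 on
#'   z-normalized covariates.
#' @param q Small positive constant, default 1e-10.
#' @return Object of class `prior_config`.
#' @export
prior_config <- function(d = 1.0, q = 1e-10) {
  stopifnot(d >= 0, q > 0)
  structure(list(d = d, q = q), class = "prior_config")
}

# Gauss-Hermite rule recast for E[g(u)], u ~ N(0,1):
# E[g(u)] = sum_k omega_k g(z_k), z = sqrt(2) x, omega = w / sqrt(pi).
gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(n) {
  key <- as.character(n)
  if (is.null(gh_cache[[key]])) {
    gh <- pracma::gaussHermite(n)
    gh_cache[[key]] <- list(z = sqrt(2) * gh$x, omega = gh$w / sqrt(pi))
  }
  gh_cache[[key]]
}

linear_predictor <- function(params, Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) != length(params$beta))
    stop(sprintf("covariate dimension mismatch: %d columns vs %d beta",
                 ncol(Z), length(params$beta)), call. = FALSE)
  as.vector(Z %*% params$beta) + params$beta0
}

#' Noise-averaged score prediction
#'
#' Predicts the mean score `a E_u[tanh(beta . Z + beta_0 + sigma_1 u)]
#' + b`, with the expectation over the covariate noise computed by
#' Gauss-Hermite quadrature (exact plug-in when `sigma1 = 0`).  The
#' predictive SD combines the quadrature variance of `a tanh(.)` with
#' the score-noise variance `sigma2^2`.  The mean always lies in the
#' fitted range `[A, B]`.
#'
#' @param params A [noise_model_params].
#' @param Z Covariate row (length p) or n x p matrix, normalized with
#'   the training constants.
#' @param nodes Gauss-Hermite node count.
#' @param plug_in If TRUE, ignore the covariate noise and evaluate the
#'   link at the mean (plug-in prediction).
#' @return Data frame with columns `mean` and `sd`.
#' @export
predict_mean <- function(params, Z, nodes = 32, plug_in = FALSE) {
  stopifnot(inherits(params, "noise_model_params"))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  eta <- linear_predictor(params, Z)
  if (plug_in || params$sigma1 == 0) {
    m <- params$a * tanh(eta) + params$b
    return(data.frame(mean = m, sd = rep(params$sigma2, length(m))))
  }
  gh <- gh_rule(nodes)
  G <- tanh(outer(eta, params$sigma1 * gh$z, "+"))
  Et <- as.vector(G %*% gh$omega)
  Et2 <- as.vector(G^2 %*% gh$omega)
  vt <- pmax(Et2 - Et^2, 0)
  data.frame(mean = params$a * Et + params$b,
             sd = sqrt(params$a^2 * vt + params$sigma2^2))
}

log_sum_exp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Regularised MAP objectives of the noise models
#'
#' `objective_double()` is the full double-noise objective: the
#' negative log of the Gaussian-integral likelihood (evaluated by
#' adaptive Gauss-Hermite quadrature, node count doubled until the
#' relative change falls below 1e-8) plus the prior terms
#' `d/2 |beta|^2 + n log(sigma2) + q/sigma2 + q/sigma1`.
#' `objective_score()` is its closed-form `sigma1 -> 0` limit (score
#' noise only); `objective_covariate()` its `sigma2 -> 0` limit
#' (covariate noise only), which is finite only while
#' `|S_i - b| < a` for every sample and `+Inf` otherwise, so the
#' half-range `a` is effectively constrained to
#' `a > max_i |S_i - b|`.
#'
#' @param params A [noise_model_params].
#' @param prior A [prior_config].
#' @param Z n x p covariate matrix.
#' @param S Length-n score vector.
#' @param nodes Initial Gauss-Hermite node count.
#' @param adaptive Double the node count until convergence.
#' @return Scalar objective value (may be `Inf` for the covariate
#'   model).
#' @export
objective_double <- function(params, prior, Z, S, nodes = 32,
                             adaptive = TRUE) {
  stopifnot(inherits(params, "noise_model_params"),
            inherits(prior, "prior_config"))
  if (params$sigma1 <= 0 || params$sigma2 <= 0)
    stop("the double-noise objective needs sigma1 > 0 and sigma2 > 0",
         call. = FALSE)
  Z <- as.matrix(Z); S <- as.numeric(S)
  if (!all(is.finite(Z))) stop("non-finite covariates", call. = FALSE)
  n <- length(S)
  if (n == 0L) stop("empty data", call. = FALSE)
  val <- double_loglik_term(params, Z, S, nodes)
  if (adaptive) {
    k <- nodes
    repeat {
      k <- 2L * k
      if (k > 512L) break
      nxt <- double_loglik_term(params, Z, S, k)
      if (abs(nxt - val) <= 1e-8 * max(1, abs(nxt))) { val <- nxt; break }
      val <- nxt
    }
  }
  val + 0.5 * prior$d * sum(params$beta^2) + n * log(params$sigma2) +
    prior$q / params$sigma2 + prior$q / params$sigma1
}

double_loglik_term <- function(params, Z, S, nodes) {
  gh <- gh_rule(nodes)
  eta <- linear_predictor(params, Z)
  G <- tanh(outer(eta, params$sigma1 * gh$z, "+"))
  R <- S - params$a * G - params$b
  H <- sweep(-R^2 / (2 * params$sigma2^2), 2L, log(gh$omega), "+")
  -sum(log_sum_exp_rows(H))
}

#' @rdname objective_double
#' @export
objective_score <- function(params, prior, Z, S) {
  stopifnot(inherits(params, "noise_model_params"),
            inherits(prior, "prior_config"))
  if (params$sigma2 <= 0)
    stop("the score-noise objective needs sigma2 > 0", call. = FALSE)
  Z <- as.matrix(Z); S <- as.numeric(S)
  if (!all(is.finite(Z))) stop("non-finite covariates", call. = FALSE)
  n <- length(S)
  r <- S - params$b - params$a * tanh(linear_predictor(params, Z))
  sum(r^2) / (2 * params$sigma2^2) + n * log(params$sigma2) +
    0.5 * prior$d * sum(params$beta^2) + prior$q / params$sigma2
}

#' @rdname objective_double
#' @export
objective_covariate <- function(params, prior, Z, S) {
  stopifnot(inherits(params, "noise_model_params"),
            inherits(prior, "prior_config"))
  if (params$sigma1 <= 0)
    stop("the covariate-noise objective needs sigma1 > 0", call. = FALSE)
  Z <- as.matrix(Z); S <- as.numeric(S)
  if (!all(is.finite(Z))) stop("non-finite covariates", call. = FALSE)
  n <- length(S)
  w <- S - params$b
  if (any(abs(w) >= params$a)) return(Inf)
  e <- atanh(w / params$a) - linear_predictor(params, Z)
  sum(e^2) / (2 * params$sigma1^2) + sum(log(params$a^2 - w^2)) +
    n * log(params$sigma1 / params$a) +
    0.5 * prior$d * sum(params$beta^2) + prior$q / params$sigma1
}

# Analytic gradients of the objectives with respect to the natural
# parameter vector (beta_1..p, beta0, a, b, sigma1?, sigma2?).  Used as
# an independent check against finite differences; the optimizer itself
# works on the reparameterized objectives with numerical derivatives.
objective_score_grad <- function(params, prior, Z, S) {
  Z <- as.matrix(Z); S <- as.numeric(S)
  n <- length(S)
  t <- tanh(linear_predictor(params, Z))
  r <- S - params$b - params$a * t
  s2 <- params$sigma2
  sech2 <- 1 - t^2
  gbeta <- as.vector(t(Z) %*% (-r * params$a * sech2 / s2^2)) +
    prior$d * params$beta
  c(gbeta,
    beta0 = sum(-r * params$a * sech2) / s2^2,
    a = sum(-r * t) / s2^2,
    b = sum(-r) / s2^2,
    sigma2 = -sum(r^2) / s2^3 + n / s2 - prior$q / s2^2)
}

objective_covariate_grad <- function(params, prior, Z, S) {
  Z <- as.matrix(Z); S <- as.numeric(S)
  n <- length(S)
  a <- params$a; s1 <- params$sigma1
  w <- S - params$b
  denom <- a^2 - w^2
  e <- atanh(w / a) - linear_predictor(params, Z)
  gbeta <- as.vector(t(Z) %*% (-e / s1^2)) + prior$d * params$beta
  c(gbeta,
    beta0 = -sum(e) / s1^2,
    a = sum(e * (-w / denom)) / s1^2 + sum(2 * a / denom) - n / a,
    b = sum(e * (-a / denom)) / s1^2 + sum(2 * w / denom),
    sigma1 = -sum(e^2) / s1^3 + n / s1 - prior$q / s1^2)
}

objective_double_grad <- function(params, prior, Z, S, nodes = 64) {
  Z <- as.matrix(Z); S <- as.numeric(S)
  n <- length(S)
  a <- params$a; s1 <- params$sigma1; s2 <- params$sigma2
  gh <- gh_rule(nodes)
  eta <- linear_predictor(params, Z)
  G <- tanh(outer(eta, s1 * gh$z, "+"))
  R <- S - a * G - params$b
  H <- sweep(-R^2 / (2 * s2^2), 2L, log(gh$omega), "+")
  mx <- apply(H, 1L, max)
  P <- exp(H - mx)
  P <- P / rowSums(P) # posterior node weights per sample
  sech2 <- 1 - G^2
  # d(-h)/dtheta summed with weights P; h = -R^2/(2 s2^2)
  common <- P * R / s2^2 # n x K
  gbeta <- as.vector(t(Z) %*% (-rowSums(common * a * sech2))) +
    prior$d * params$beta
  gb0 <- -sum(common * a * sech2)
  ga <- -sum(common * G)
  gb <- -sum(common)
  gs1 <- -sum(common * a * sech2 * rep(gh$z, each = n))
  gs2 <- -sum(P * R^2) / s2^3 + n / s2 - prior$q / s2^2
  c(gbeta, beta0 = gb0, a = ga, b = gb,
    sigma1 = gs1 - prior$q / s1^2, sigma2 = gs2)
}

#' Fit a noise model by multi-start MAP optimization
#'
#' Minimizes the chosen variant's regularised objective over the model
#' parameters with a quasi-Newton optimizer on an unconstrained
#' reparameterization: the half-range is `a = exp(alpha)` (so
#' `B >= A` holds structurally), noise strengths enter as
#' `log(sigma)`, and for the covariate-noise model
#' `a = max_i |S_i - b| + exp(alpha)` so the domain constraint holds at
#' every iterate.  The best of `n_starts` seeded starts is returned;
#' identical seed and data give an identical fit.
#'
#' @param x A `feature_matrix` from [assemble_feature_matrix()], or a
#'   numeric covariate matrix (then give `scores`).
#' @param scores Score vector when `x` is a plain matrix.
#' @param variant `"covariate"`, `"score"` or `"double"`.
#' @param prior A [prior_config].
#' @param n_starts Number of optimizer starts (default 16).
#' @param seed Optional integer seed controlling the random starts.
#' @param nodes Gauss-Hermite node count for the double model.
#' @param compute_errors Also compute curvature standard errors
#'   (default TRUE).
#'
#' @return Object of class `kinscore_fit`: `params`
#'   ([noise_model_params]), `std_errors`, `objective_value`,
#'   `variant`, `converged`, `fragile`, `n`, `p`, `seed`, `prior`,
#'   plus the training data and any normalization metadata.
#' @export
fit_noise_model <- function(x, scores = NULL,
                            variant = c("covariate", "score", "double"),
                            prior = prior_config(), n_starts = 16,
                            seed = NULL, nodes = 32,
                            compute_errors = TRUE) {
  variant <- match.arg(variant)
  dat <- resolve_data(x, scores)
  Z <- dat$Z; S <- dat$S
  n <- nrow(Z); p <- ncol(Z)
  if (n <= p + 5)
    stop("need n > p + 5 samples to fit", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  obj_free <- function(par) {
    pr <- unpack_params(par, p, variant, S)
    val <- switch(variant,
      covariate = objective_covariate(pr, prior, Z, S),
      score = objective_score(pr, prior, Z, S),
      double = objective_double(pr, prior, Z, S, nodes = nodes,
                                adaptive = FALSE))
    if (!is.finite(val)) 1e12 else val
  }
  b0 <- stats::median(S)
  maxdev <- max(abs(S - b0))
  sig_cycle <- c(0.1, 0.5, 1)
  best <- NULL
  n_fail <- 0L
  for (s in seq_len(n_starts)) {
    beta_s <- stats::rnorm(p, 0, 0.5)
    beta0_s <- stats::rnorm(1, 0, 0.5)
    sig_s <- sig_cycle[(s - 1L) %% 3L + 1L]
    par0 <- pack_start(beta_s, beta0_s, b0, maxdev, sig_s, variant)
    res <- tryCatch(
      stats::nlminb(par0, obj_free,
                    control = list(iter.max = 500, eval.max = 1500)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective) ||
        res$objective >= 1e12) { n_fail <- n_fail + 1L; next }
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best))
    stop(sprintf("no finite optimum found after %d starts (%d failures)",
                 n_starts, n_fail), call. = FALSE)
  params <- unpack_params(best$par, p, variant, S)
  fit <- structure(list(
    params = params, std_errors = NULL,
    objective_value = best$objective,
    variant = paste0(variant,
                     if (variant %in% c("covariate", "score")) "_noise"
                     else ""),
    converged = best$convergence == 0, fragile = FALSE,
    n = n, p = p, seed = seed, n_starts = n_starts,
    prior = prior, nodes = nodes,
    optimizer = list(iterations = best$iterations,
                     message = best$message, failures = n_fail),
    Z = Z, S = S, columns = dat$columns,
    normalization = dat$normalization),
    class = "kinscore_fit")
  if (compute_errors) fit <- param_errors(fit)
  fit
}

resolve_data <- function(x, scores) {
  if (inherits(x, "feature_matrix")) {
    list(Z = x$Z, S = x$S, columns = x$columns,
         normalization = list(centers = x$centers, scales = x$scales,
                              log_shifts = x$log_shifts,
                              source_columns = x$source_columns))
  } else {
    Z <- as.matrix(x)
    if (is.null(scores)) stop("'scores' required with a plain matrix",
                              call. = FALSE)
    if (length(scores) != nrow(Z))
      stop("'scores' length must match rows of 'x'", call. = FALSE)
    list(Z = Z, S = as.numeric(scores),
         columns = colnames(Z) %||% paste0("z", seq_len(ncol(Z))),
         normalization = NULL)
  }
}

# free-parameter layout: beta(1..p), beta0, b, alpha, [log sigma1], [log sigma2]
pack_start <- function(beta, beta0, b, maxdev, sig, variant) {
  alpha <- switch(variant,
    covariate = log(0.05 * max(maxdev, 1e-8)),
    log(1.05 * max(maxdev, 1e-8)))
  c(beta, beta0, b, alpha,
    switch(variant,
           covariate = log(sig),
           score = log(sig),
           double = c(log(sig), log(sig))))
}

unpack_params <- function(par, p, variant, S) {
  beta <- par[seq_len(p)]
  beta0 <- par[p + 1L]
  b <- par[p + 2L]
  alpha <- par[p + 3L]
  a <- if (variant == "covariate") max(abs(S - b)) + exp(alpha)
       else exp(alpha)
  s <- exp(par[-seq_len(p + 3L)])
  sigma1 <- switch(variant, covariate = s[1], score = 0, double = s[1])
  sigma2 <- switch(variant, covariate = 0, score = s[1], double = s[2])
  noise_model_params_ab(beta, beta0, a = a, b = b,
                        sigma1 = sigma1, sigma2 = sigma2)
}

#' Curvature standard errors for a fitted noise model
#'
#' Standard errors are the square roots of the diagonal of the inverse
#' Hessian of the regularised objective at the optimum, in the natural
#' parameterization `(beta, beta0, a, b, sigma...)`.  The Hessian is
#' computed by central finite differences with steps scaled to the
#' parameter magnitude.  If the Hessian is not positive definite the
#' affected entries are `NA` and the fit is flagged fragile.
#'
#' @param fit A `kinscore_fit`.
#' @return The fit with `std_errors` (named vector) and `fragile` set.
#' @export
param_errors <- function(fit) {
  stopifnot(inherits(fit, "kinscore_fit"))
  th <- natural_theta(fit)
  f <- natural_objective_fn(fit)
  H <- fd_hessian(f, th$value)
  se <- rep(NA_real_, length(th$value))
  fragile <- FALSE
  inv <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(inv)) {
    fragile <- TRUE
  } else {
    dg <- diag(inv)
    bad <- !is.finite(dg) | dg <= 0
    se[!bad] <- sqrt(dg[!bad])
    fragile <- any(bad)
  }
  names(se) <- th$names
  fit$std_errors <- se
  fit$fragile <- fragile
  fit
}

natural_theta <- function(fit) {
  p <- fit$p
  pr <- fit$params
  nm <- c(paste0("beta_", fit$columns), "beta0", "a", "b")
  v <- c(pr$beta, pr$beta0, pr$a, pr$b)
  if (fit$variant %in% c("covariate_noise", "double")) {
    v <- c(v, pr$sigma1); nm <- c(nm, "sigma1")
  }
  if (fit$variant %in% c("score_noise", "double")) {
    v <- c(v, pr$sigma2); nm <- c(nm, "sigma2")
  }
  list(value = v, names = nm)
}

natural_objective_fn <- function(fit) {
  p <- fit$p
  variant <- fit$variant
  prior <- fit$prior
  Z <- fit$Z; S <- fit$S
  nodes <- fit$nodes
  function(th) {
    beta <- th[seq_len(p)]
    beta0 <- th[p + 1L]; a <- th[p + 2L]; b <- th[p + 3L]
    if (a <= 0) return(Inf)
    rest <- th[-seq_len(p + 3L)]
    pr <- switch(variant,
      covariate_noise = noise_model_params_ab(beta, beta0, a, b,
                                              sigma1 = rest[1]),
      score_noise = noise_model_params_ab(beta, beta0, a, b,
                                          sigma2 = rest[1]),
      double = noise_model_params_ab(beta, beta0, a, b,
                                     sigma1 = rest[1], sigma2 = rest[2]),
      linear = NULL)
    switch(variant,
      covariate_noise = objective_covariate(pr, prior, Z, S),
      score_noise = objective_score(pr, prior, Z, S),
      double = objective_double(pr, prior, Z, S, nodes = nodes,
                                adaptive = FALSE),
      linear = linear_objective(beta, beta0, rest[1], prior, Z, S))
  }
}

fd_hessian <- function(f, x, rel_step = 1e-4) {
  k <- length(x)
  h <- pmax(abs(x) * rel_step, 1e-6)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < k) for (j in (i + 1L):k) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) -
         f(x - ei + ej) + f(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

linear_objective <- function(beta, beta0, sigma, prior, Z, S) {
  if (sigma <= 0) return(Inf)
  r <- S - as.vector(Z %*% beta) - beta0
  sum(r^2) / (2 * sigma^2) + length(S) * log(sigma) +
    0.5 * prior$d * sum(beta^2) + prior$q / sigma
}

#' Linear baseline with the same ridge prior
#'
#' Fits the unbounded linear model `S = beta . Z + beta0 + sigma u` by
#' maximum (penalized) likelihood.  Solved by alternating the
#' closed-form ridge update for `(beta, beta0)` given `sigma` with the
#' noise update `sigma^2 = SSE/n`, iterated to convergence.
#' Predictions are deliberately not clamped, exposing the failure mode
#' of mapping unbounded estimates onto a bounded clinical scale.
#'
#' @inheritParams fit_noise_model
#' @return A `kinscore_fit` with `variant = "linear"`.
#' @export
fit_linear_baseline <- function(x, scores = NULL, prior = prior_config(),
                                compute_errors = TRUE) {
  dat <- resolve_data(x, scores)
  Z <- dat$Z; S <- dat$S
  n <- nrow(Z); p <- ncol(Z)
  if (n <= p + 2) stop("need n > p + 2 samples", call. = FALSE)
  X <- cbind(Z, 1)
  if (qr(X)$rank < ncol(X)) stop("singular design", call. = FALSE)
  D <- diag(c(rep(1, p), 0)) # intercept unpenalized
  XtX <- crossprod(X); XtS <- crossprod(X, S)
  sigma2 <- stats::var(S)
  theta <- NULL
  for (it in 1:200) {
    theta_new <- solve(XtX + prior$d * sigma2 * D, XtS)
    r <- S - as.vector(X %*% theta_new)
    sigma2_new <- max(sum(r^2) / n, 1e-20)
    done <- !is.null(theta) &&
      max(abs(theta_new - theta)) < 1e-12 &&
      abs(sigma2_new - sigma2) < 1e-14 * max(1, sigma2)
    theta <- theta_new; sigma2 <- sigma2_new
    if (done) break
  }
  beta <- theta[seq_len(p)]; beta0 <- theta[p + 1L]
  sigma <- sqrt(sigma2)
  params <- structure(list(beta = as.numeric(beta), beta0 = beta0,
                           A = -Inf, B = Inf, sigma1 = 0, sigma2 = sigma,
                           a = Inf, b = 0),
                      class = "noise_model_params")
  fit <- structure(list(
    params = params, std_errors = NULL,
    objective_value = linear_objective(beta, beta0, sigma, prior, Z, S),
    variant = "linear", converged = TRUE, fragile = FALSE,
    n = n, p = p, seed = NULL, n_starts = 1L, prior = prior,
    nodes = NA_integer_, optimizer = list(iterations = it),
    Z = Z, S = S, columns = dat$columns,
    normalization = dat$normalization),
    class = "kinscore_fit")
  if (compute_errors) {
    th <- c(beta, beta0, sigma)
    f <- function(v) linear_objective(v[seq_len(p)], v[p + 1L], v[p + 2L],
                                      prior, Z, S)
    H <- fd_hessian(f, th)
    inv <- tryCatch(solve(H), error = function(e) NULL)
    se <- rep(NA_real_, length(th))
    if (!is.null(inv)) {
      dg <- diag(inv)
      ok <- is.finite(dg) & dg > 0
      se[ok] <- sqrt(dg[ok])
      fit$fragile <- any(!ok)
    } else fit$fragile <- TRUE
    names(se) <- c(paste0("beta_", fit$columns), "beta0", "sigma")
    fit$std_errors <- se
  }
  fit
}

#' @export
print.kinscore_fit <- function(x, ...) {
  cat(sprintf("<kinscore_fit> %s model, n=%d, p=%d, objective=%.4f%s\n",
              x$variant, x$n, x$p, x$objective_value,
              if (isTRUE(x$fragile)) " (fragile curvature)" else ""))
  invisible(x)
}

#' Predict scores from a fitted model
#'
#' @param object A `kinscore_fit`.
#' @param newdata Normalized covariate matrix, or a raw feature data
#'   frame when the fit carries normalization metadata.
#' @param ... Passed to [predict_mean()] for the nonlinear variants.
#' @return Numeric vector of predicted scores (unclamped for the
#'   linear baseline).
#' @export
predict.kinscore_fit <- function(object, newdata = NULL, ...) {
  Z <- if (is.null(newdata)) object$Z
       else if (is.data.frame(newdata) && !is.null(object$normalization)) {
         fm <- structure(c(object$normalization,
                           list(columns = object$columns)),
                         class = "feature_matrix")
         apply_feature_normalization(fm, newdata)
       } else as.matrix(newdata)
  if (object$variant == "linear")
    return(as.vector(Z %*% object$params$beta) + object$params$beta0)
  predict_mean(object$params, Z, ...)$mean
}

#' Save and load a fitted model as structured text
#'
#' Serializes the fit (variant, columns, normalization constants,
#' parameters, standard errors, prior, seed) to JSON at full precision
#' so that a write/read round trip reproduces the model exactly.
#'
#' @param fit A `kinscore_fit`.
#' @param path File path for the JSON model file.
#' @return `load_model()` returns the restored `kinscore_fit` (without
#'   the training data).
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "kinscore_fit"))
  obj <- list(
    package = "kinscore", format = 1L,
    variant = fit$variant, columns = fit$columns,
    params = fit$params[c("beta", "beta0", "A", "B", "sigma1", "sigma2")],
    std_errors = as.list(fit$std_errors),
    objective_value = fit$objective_value,
    converged = fit$converged, fragile = fit$fragile,
    n = fit$n, p = fit$p, seed = fit$seed, n_starts = fit$n_starts,
    prior = unclass(fit$prior), nodes = fit$nodes,
    normalization = if (is.null(fit$normalization)) NULL else list(
      centers = as.list(fit$normalization$centers),
      scales = as.list(fit$normalization$scales),
      log_shifts = as.list(fit$normalization$log_shifts),
      source_columns = fit$normalization$source_columns))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$package, "kinscore"))
    stop("not a kinscore model file", call. = FALSE)
  p <- obj$params
  params <- if (is.finite(p$A)) {
    noise_model_params(p$beta, p$beta0, p$A, p$B, p$sigma1, p$sigma2)
  } else {
    structure(list(beta = p$beta, beta0 = p$beta0, A = -Inf, B = Inf,
                   sigma1 = 0, sigma2 = p$sigma2, a = Inf, b = 0),
              class = "noise_model_params")
  }
  norm <- obj$normalization
  if (!is.null(norm)) {
    norm$centers <- unlist(norm$centers)
    norm$scales <- unlist(norm$scales)
    norm$log_shifts <- unlist(norm$log_shifts)
  }
  structure(list(
    params = params, std_errors = unlist(obj$std_errors),
    objective_value = obj$objective_value, variant = obj$variant,
    converged = obj$converged, fragile = obj$fragile,
    n = obj$n, p = obj$p, seed = obj$seed, n_starts = obj$n_starts,
    prior = prior_config(d = as.numeric(obj$prior$d),
                         q = as.numeric(obj$prior$q)),
    nodes = obj$nodes, optimizer = NULL,
    Z = NULL, S = NULL, columns = obj$columns,
    normalization = norm),
    class = "kinscore_fit")
}
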