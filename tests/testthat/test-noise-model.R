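prior0 <- prior_config()

test_that("predict_mean is the noise-averaged bounded prediction", {
  # beta = 0, sigma1 = 0: the midpoint of the range for any Z
  p0 <- noise_model_params(numeric(3), 0, A = 10, B = 60)
  expect_equal(predict_mean(p0, c(5, -2, 1))$mean, 35)

  # saturation toward the range ends
  p1 <- noise_model_params(1, 0, A = 10, B = 60)
  expect_equal(predict_mean(p1, 50)$mean, 60, tolerance = 1e-8)
  expect_equal(predict_mean(p1, -50)$mean, 10, tolerance = 1e-8)

  # hand-computed plug-in value with the reported FM-UE hyperparameters
  p2 <- noise_model_params_ab(numeric(0), 0.370, a = 32.72, b = 34.55)
  expect_equal(predict_mean(p2, matrix(numeric(0), 1, 0))$mean,
               32.72 * tanh(0.370) + 34.55, tolerance = 1e-12)

  # quadrature mean against a dense numerical integral
  p3 <- noise_model_params_ab(c(0.8, -0.3), 0.2, a = 30, b = 35,
                              sigma1 = 0.7, sigma2 = 2)
  z <- c(0.4, -1.1)
  eta <- sum(p3$beta * z) + p3$beta0
  u <- seq(-8, 8, length.out = 20001)
  du <- u[2] - u[1]
  w <- stats::dnorm(u) * du
  m_ref <- 30 * sum(w * tanh(eta + 0.7 * u)) + 35
  pm <- predict_mean(p3, z)
  expect_equal(pm$mean, m_ref, tolerance = 1e-8)
  v_ref <- 30^2 * (sum(w * tanh(eta + 0.7 * u)^2) -
                     sum(w * tanh(eta + 0.7 * u))^2) + 4
  expect_equal(pm$sd, sqrt(v_ref), tolerance = 1e-6)

  expect_error(predict_mean(p3, c(1, 2, 3)), "dimension mismatch")
})

test_that("predictions stay in [A, B] for random parameters", {
  set.seed(20)
  for (i in 1:200) {
    p <- sample(1:4, 1)
    A <- stats::runif(1, -20, 40)
    B <- A + stats::runif(1, 0, 80)
    th <- noise_model_params(stats::rnorm(p, 0, 2), stats::rnorm(1),
                             A, B, sigma1 = stats::rexp(1),
                             sigma2 = stats::rexp(1))
    Z <- matrix(stats::rcauchy(50 * p), 50, p) # heavy-tailed rows
    m <- predict_mean(th, Z)$mean
    expect_true(all(m >= A - 1e-9 & m <= B + 1e-9))
  }
})

test_that("objective_score matches its closed form and penalties", {
  d <- gen_tanh_data(20, c(1, -0.5, 0.3), 0.2, a = 16, b = 30,
                     sigma1 = 0, sigma2 = 0.5, seed = 21)
  # perfect fit leaves only the noise and prior terms
  truth <- noise_model_params_ab(c(1, -0.5, 0.3), 0.2, a = 16, b = 30,
                                 sigma2 = 0.8)
  S_perfect <- 16 * tanh(d$Z %*% c(1, -0.5, 0.3) + 0.2) + 30
  expect_equal(objective_score(truth, prior0, d$Z, S_perfect),
               20 * log(0.8) + 0.5 * sum(c(1, -0.5, 0.3)^2) +
                 1e-10 / 0.8,
               tolerance = 1e-10)
  # residual term scales as SSE / (2 sigma2^2)
  r <- d$S - 30 - 16 * tanh(d$Z %*% c(1, -0.5, 0.3) + 0.2)
  expect_equal(objective_score(truth, prior0, d$Z, d$S) -
                 objective_score(truth, prior0, d$Z, S_perfect),
               sum(r^2) / (2 * 0.8^2), tolerance = 1e-9)
  # doubling the ridge adds exactly d |beta|^2 / 2
  pr2 <- prior_config(d = 2)
  expect_equal(objective_score(truth, pr2, d$Z, d$S) -
                 objective_score(truth, prior0, d$Z, d$S),
               0.5 * sum(c(1, -0.5, 0.3)^2), tolerance = 1e-10)
})

test_that("objective_covariate matches a literal transcription", {
  # 3-point hand-computable case
  Z <- matrix(c(0.5, -1, 0.2), 3, 1)
  S <- c(28, 35, 31)
  th <- noise_model_params_ab(0.7, -0.1, a = 10, b = 30, sigma1 = 0.6)
  lit <- sum((atanh((S - 30) / 10) - 0.7 * Z[, 1] + 0.1)^2) /
    (2 * 0.6^2) + sum(log(10^2 - (S - 30)^2)) + 3 * log(0.6 / 10) +
    0.5 * 0.7^2 + 1e-10 / 0.6
  expect_equal(objective_covariate(th, prior0, Z, S), lit,
               tolerance = 1e-12)

  # S = b reduces the residual to the linear predictor
  th2 <- noise_model_params_ab(0.7, -0.1, a = 10, b = 31, sigma1 = 0.6)
  expect_equal(objective_covariate(th2, prior0, Z, rep(31, 3)) -
                 (sum(log(rep(100, 3))) + 3 * log(0.06) +
                    0.5 * 0.49 + 1e-10 / 0.6),
               sum((0.7 * Z[, 1] - 0.1)^2) / (2 * 0.36),
               tolerance = 1e-10)

  # outside |S - b| < a the objective is +Inf
  th3 <- noise_model_params_ab(0.7, -0.1, a = 4, b = 30, sigma1 = 0.6)
  expect_identical(objective_covariate(th3, prior0, Z, S), Inf)
  expect_identical(objective_covariate(th2, prior0, Z, c(41, 31, 31)),
                   Inf)
})

test_that("objective_double approaches the score model as sigma1 -> 0", {
  d <- gen_tanh_data(20, c(0.8, -0.4), 0.1, a = 14, b = 32,
                     sigma1 = 0, sigma2 = 1, seed = 22)
  th_eps <- noise_model_params_ab(c(0.8, -0.4), 0.1, a = 14, b = 32,
                                  sigma1 = 1e-6, sigma2 = 1.2)
  th_0 <- noise_model_params_ab(c(0.8, -0.4), 0.1, a = 14, b = 32,
                                sigma2 = 1.2)
  # the diverging q/sigma1 prior weight is excluded from the limit
  gap <- abs((objective_double(th_eps, prior0, d$Z, d$S) -
                prior0$q / 1e-6) -
               objective_score(th_0, prior0, d$Z, d$S))
  expect_lt(gap, 1e-6)
})

test_that("double-noise quadrature matches a brute-force integral", {
  # single data point, dense trapezoid integration over +-8 as oracle
  Z <- matrix(c(0.3, -0.6), 1, 2)
  S <- 39
  th <- noise_model_params_ab(c(0.9, 0.4), -0.2, a = 12, b = 33,
                              sigma1 = 0.8, sigma2 = 1.5)
  u <- seq(-8, 8, length.out = 10001)
  du <- u[2] - u[1]
  integ <- sum(stats::dnorm(u) * du *
                 exp(-(S - 12 * tanh(sum(c(0.9, 0.4) * Z) - 0.2 +
                                       0.8 * u) - 33)^2 / (2 * 1.5^2)))
  ref <- -log(integ) + 0.5 * sum(c(0.9, 0.4)^2) + log(1.5) +
    1e-10 / 1.5 + 1e-10 / 0.8
  expect_equal(objective_double(th, prior0, Z, S), ref,
               tolerance = 1e-8)
})

test_that("finite differences confirm the analytic gradients", {
  set.seed(23)
  d <- gen_tanh_data(15, c(0.7, -0.3, 0.2), 0.1, a = 15, b = 31,
                     sigma1 = 0.4, sigma2 = 0.8, seed = 23)
  wrap <- function(variant) function(v) {
    th <- noise_model_params_ab(v[1:3], v[4], a = v[5], b = v[6],
                                sigma1 = v[7], sigma2 = v[8])
    switch(variant,
           score = objective_score(th, prior0, d$Z, d$S),
           cov = objective_covariate(th, prior0, d$Z, d$S),
           dbl = objective_double(th, prior0, d$Z, d$S, nodes = 64,
                                  adaptive = FALSE))
  }
  for (rep in 1:6) {
    v <- c(stats::rnorm(3, 0, 0.5), stats::rnorm(1, 0, 0.3),
           max(abs(d$S - 31)) + stats::runif(1, 1, 4),
           31 + stats::rnorm(1, 0, 0.5),
           stats::runif(1, 0.3, 1), stats::runif(1, 0.5, 1.5))
    th <- noise_model_params_ab(v[1:3], v[4], a = v[5], b = v[6],
                                sigma1 = v[7], sigma2 = v[8])
    gs <- kinscore:::objective_score_grad(th, prior0, d$Z, d$S)
    gc <- kinscore:::objective_covariate_grad(th, prior0, d$Z, d$S)
    gd <- kinscore:::objective_double_grad(th, prior0, d$Z, d$S,
                                           nodes = 64)
    fs <- pracma::grad(wrap("score"), v, heps = 1e-6)
    fc <- pracma::grad(wrap("cov"), v, heps = 1e-6)
    fd <- pracma::grad(wrap("dbl"), v, heps = 1e-6)
    # score model has no sigma1 dependence, covariate none on sigma2
    expect_equal(unname(gs), fs[c(1:6, 8)], tolerance = 1e-5)
    expect_equal(unname(gc), fc[1:7], tolerance = 1e-5)
    expect_equal(unname(gd), fd, tolerance = 1e-5)
  }
})

test_that("fitting recovers planted parameters and is deterministic", {
  d <- gen_tanh_data(400, c(0.6, -0.4, 0.25), 0.3, a = 31, b = 35,
                     sigma1 = 0.5, sigma2 = 0, seed = 31)
  fit <- fit_noise_model(d$Z, d$S, variant = "covariate",
                         n_starts = 8, seed = 42)
  expect_true(fit$converged)
  expect_true(all(abs(fit$params$beta - c(0.6, -0.4, 0.25)) <=
                    3 * fit$std_errors[1:3]))
  expect_equal(fit$params$a, 31, tolerance = 0.1 * 31)
  expect_equal(fit$params$sigma1, 0.5, tolerance = 0.15)

  fit2 <- fit_noise_model(d$Z, d$S, variant = "covariate",
                          n_starts = 8, seed = 42)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$objective_value, fit2$objective_value)

  # null design: no fitted coefficient leaves the noise band
  d0 <- gen_tanh_data(200, c(0, 0, 0), 0.1, a = 30, b = 35,
                      sigma1 = 0.5, sigma2 = 0, seed = 33)
  fit0 <- fit_noise_model(d0$Z, d0$S, variant = "covariate",
                          n_starts = 8, seed = 7)
  expect_true(all(abs(fit0$params$beta) < 3 * fit0$std_errors[1:3]))

  # near-noiseless tanh data is almost interpolated
  dn <- gen_tanh_data(150, c(0.8, -0.5), 0.2, a = 28, b = 34,
                      sigma1 = 0.02, sigma2 = 0, seed = 34)
  fitn <- fit_noise_model(dn$Z, dn$S, variant = "covariate",
                          n_starts = 8, seed = 8)
  pred <- predict(fitn)
  expect_lt(sqrt(mean((pred - dn$S)^2)), 0.5)

  expect_error(fit_noise_model(d$Z[1:6, ], d$S[1:6],
                               variant = "covariate"),
               "n > p \\+ 5")
})

test_that("the fit is invariant under row permutation", {
  d <- gen_tanh_data(120, c(0.5, -0.3), 0, a = 20, b = 35,
                     sigma1 = 0.4, sigma2 = 0, seed = 35)
  idx <- sample(120)
  f1 <- fit_noise_model(d$Z, d$S, variant = "covariate", n_starts = 4,
                        seed = 5, compute_errors = FALSE)
  f2 <- fit_noise_model(d$Z[idx, ], d$S[idx], variant = "covariate",
                        n_starts = 4, seed = 5, compute_errors = FALSE)
  expect_equal(f1$objective_value, f2$objective_value, tolerance = 1e-6)
  expect_equal(f1$params$beta, f2$params$beta, tolerance = 1e-4)
  th <- f1$params
  expect_equal(objective_covariate(th, prior0, d$Z, d$S),
               objective_covariate(th, prior0, d$Z[idx, ], d$S[idx]),
               tolerance = 1e-10)
})

test_that("curvature standard errors behave like 1/sqrt(n)", {
  d1 <- gen_tanh_data(200, c(0.6, -0.4, 0.25), 0.3, a = 31, b = 35,
                      sigma1 = 0.5, sigma2 = 0, seed = 36)
  d4 <- gen_tanh_data(800, c(0.6, -0.4, 0.25), 0.3, a = 31, b = 35,
                      sigma1 = 0.5, sigma2 = 0, seed = 36)
  f1 <- fit_noise_model(d1$Z, d1$S, variant = "covariate",
                        n_starts = 6, seed = 2)
  f4 <- fit_noise_model(d4$Z, d4$S, variant = "covariate",
                        n_starts = 6, seed = 2)
  expect_true(all(f1$std_errors > 0))
  ratio <- stats::median(f1$std_errors / f4$std_errors)
  expect_gt(ratio, 2 * 0.7)
  expect_lt(ratio, 2 * 1.3)
})

test_that("the linear baseline matches ridge algebra and is unbounded", {
  set.seed(37)
  Z <- matrix(stats::rnorm(300), 100, 3)
  S <- as.vector(Z %*% c(5, -3, 2)) + 40 + stats::rnorm(100, 0, 2)
  fit <- fit_linear_baseline(Z, S, prior = prior_config(d = 1))
  # oracle: iterate the profiled normal equations independently
  sig2 <- stats::var(S)
  X <- cbind(Z, 1); D <- diag(c(1, 1, 1, 0))
  for (i in 1:300) {
    th <- solve(crossprod(X) + 1 * sig2 * D, crossprod(X, S))
    sig2 <- sum((S - X %*% th)^2) / 100
  }
  expect_equal(fit$params$beta, th[1:3], tolerance = 1e-8)
  expect_equal(fit$params$beta0, th[4], tolerance = 1e-8)
  expect_equal(fit$params$sigma2, sqrt(sig2), tolerance = 1e-8)

  # exactly linear noiseless data with no ridge: exact recovery
  S0 <- as.vector(Z %*% c(2, 1, -1)) + 10
  f0 <- fit_linear_baseline(Z, S0, prior = prior_config(d = 1e-12))
  expect_equal(f0$params$beta, c(2, 1, -1), tolerance = 1e-6)
  expect_lt(f0$params$sigma2, 1e-4)

  # heavy-tailed covariates push linear predictions out of range while
  # the bounded model never leaves [A, B]
  set.seed(38)
  d <- gen_tanh_data(100, c(0.9, -0.5), 0.2, a = 31, b = 35,
                     sigma1 = 0.3, sigma2 = 0, seed = 38)
  lin <- fit_linear_baseline(d$Z, d$S)
  tanh_fit <- fit_noise_model(d$Z, d$S, variant = "covariate",
                              n_starts = 6, seed = 3,
                              compute_errors = FALSE)
  Zt <- matrix(stats::rcauchy(400, scale = 3), 200, 2)
  lp <- predict(lin, Zt)
  bp <- predict(tanh_fit, Zt)
  expect_gt(sum(lp > 66 | lp < 4), 0)
  expect_true(all(bp >= tanh_fit$params$A - 1e-9 &
                    bp <= tanh_fit$params$B + 1e-9))

  expect_error(fit_linear_baseline(cbind(Z, Z[, 1]), S), "singular")
})

test_that("model persistence round-trips exactly", {
  d <- gen_tanh_data(80, c(0.5, -0.2), 0.1, a = 25, b = 35,
                     sigma1 = 0.4, sigma2 = 0, seed = 39)
  fit <- fit_noise_model(d$Z, d$S, variant = "covariate", n_starts = 4,
                         seed = 12)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(fit, f)
  fit2 <- load_model(f)
  expect_identical(fit2$params$beta, fit$params$beta)
  expect_identical(fit2$params$A, fit$params$A)
  expect_identical(fit2$params$sigma1, fit$params$sigma1)
  expect_identical(unname(fit2$std_errors), unname(fit$std_errors))
  expect_identical(fit2$variant, fit$variant)
  expect_identical(fit2$prior$d, fit$prior$d)
})
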