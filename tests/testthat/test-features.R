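test_that("work_area equals an independent hull implementation", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(10:800, 1)
    x <- stats::runif(n, -0.3, 0.3)
    y <- stats::runif(n, -0.2, 0.4)
    p <- make_path(x, frontal = y)
    expect_equal(work_area(p), oracle_hull_area(x, y),
                 tolerance = 1e-12)
  }

  # unit square with interior points
  x <- c(0, 1, 1, 0, stats::runif(500))
  y <- c(0, 0, 1, 1, stats::runif(500))
  expect_equal(work_area(make_path(x, frontal = y)), 1)

  # degenerate clouds
  expect_equal(work_area(make_path(1:9 / 10, frontal = 1:9 / 10)), 0)
  expect_equal(work_area(make_path(rep(0.2, 5), frontal = rep(0.1, 5))),
               0)
  expect_error(work_area(make_path(1:5 / 10)), "requires 2-D")
})

test_that("work_area is translation-invariant and scales as s^2", {
  set.seed(12)
  x <- stats::runif(300); y <- stats::runif(300)
  a0 <- work_area(make_path(x, frontal = y))
  expect_equal(work_area(make_path(x + 5, frontal = y - 2)), a0,
               tolerance = 1e-12)
  expect_equal(work_area(make_path(2.5 * x, frontal = 2.5 * y)),
               2.5^2 * a0, tolerance = 1e-12)
})

test_that("distance_covered sums segment lengths and is additive", {
  # two samples one metre apart
  expect_equal(distance_covered(make_path(c(0, 1))), 1)
  # 100-segment zigzag of 0.1 m each
  zig <- cumsum(c(0, rep(c(0.1, -0.1), 50)))
  expect_equal(distance_covered(make_path(zig)), 10)
  # concatenation at a shared endpoint is additive
  set.seed(3)
  v <- cumsum(stats::rnorm(101)) * 0.01
  whole <- distance_covered(make_path(v))
  first <- distance_covered(make_path(v[1:51]))
  second <- distance_covered(make_path(v[51:101]))
  expect_equal(first + second, whole, tolerance = 1e-12)
  # both axes contribute
  expect_equal(distance_covered(make_path(c(0, 3), frontal = c(0, 4))), 5)
})

test_that("max_reaching_speed uses raw finite differences", {
  # uniform motion at v
  expect_equal(max_reaching_speed(make_path((0:99) * 0.012)), 1.2)
  # hand-computed two-difference example: [0, 0.02, 0.05] at 0.01 s
  expect_equal(max_reaching_speed(make_path(c(0, 0.02, 0.05))), 3)
  # stationary
  expect_equal(max_reaching_speed(make_path(rep(0.3, 10))), 0)
  # a one-sample glitch is kept, not filtered
  v <- rep(0, 100); v[50] <- 0.5
  expect_equal(max_reaching_speed(make_path(v)), 50)
})

test_that("performance_rate is the hit fraction", {
  ev <- data.frame(time = 1:10,
                   outcome = c(rep("hit", 7), rep("miss", 3)))
  expect_equal(performance_rate(ev), 0.7)
  expect_equal(performance_rate(data.frame(time = 1, outcome = "hit")), 1)
  expect_error(performance_rate(data.frame(time = numeric(),
                                           outcome = character())),
               "no targets")
})

test_that("windowed descriptors average over sliding windows", {
  tm <- (0:19999) * 0.01 # 200 s
  # constant position
  expect_equal(windowed_max_range(make_path(rep(1, 20000))), 0)
  # sinusoid of period 10 s: every 64 s window spans full cycles
  v <- 0.25 * sin(2 * pi * tm / 10)
  expect_equal(windowed_max_range(hand_path(tm, v)), 0.5,
               tolerance = 1e-3)
  # window longer than the session falls back to the global range
  short <- make_path(seq(0, 1, length.out = 500)) # 5 s
  expect_warning(r <- windowed_max_range(short), "single whole-session")
  expect_equal(r, 1)
  # windowed max speed of uniform motion is the uniform speed
  expect_equal(windowed_max_speed(make_path(tm * 0.02)), 0.02,
               tolerance = 1e-9)
  # brute-force oracle on a short series
  set.seed(4)
  v <- cumsum(stats::rnorm(400)) * 0.01
  p <- make_path(v)
  k <- 101L # 1 s window at 0.01 s steps
  brute <- mean(vapply(1:(400 - k + 1), function(i)
    diff(range(v[i:(i + k - 1)])), numeric(1)))
  expect_equal(windowed_max_range(p, window_s = 1), brute,
               tolerance = 1e-12)
})

test_that("second-order features build diffs, logs and chronicity", {
  f <- list(work_area = 0.5, distance_covered = 30,
            max_reaching_speed = 2, smoothness = 1.1, tgdm = 0.06,
            performance = 0.75, difficulty = 0.4)
  # identical limbs: all diffs vanish
  so <- second_order_features(f, f, list(days_post_stroke = 400))
  diffs <- unlist(so[startsWith(names(so), "Diff.")])
  expect_true(all(diffs == 0))
  expect_equal(so$Log.work_area, log(0.5))
  expect_identical(so$chronicity, "chronic")

  g <- utils::modifyList(f, list(tgdm = 0.09, work_area = 0.8))
  so2 <- second_order_features(f, g, list(days_post_stroke = 10))
  expect_equal(so2$Diff.tgdm, 0.03)
  expect_equal(so2$Diff.work_area, 0.3)
  expect_identical(so2$chronicity, "acute")

  # non-positive values defer to the assembly shift rule
  h <- utils::modifyList(f, list(difficulty = -0.1))
  expect_warning(so3 <- second_order_features(h, g, list()),
                 "shift rule")
  expect_true(is.na(so3$Log.difficulty))

  expect_identical(chronicity_category(c(10, 30, 180, 181)),
                   c("acute", "subacute", "subacute", "chronic"))
})

test_that("feature matrix assembly normalizes with stored constants", {
  set.seed(5)
  df <- data.frame(a = stats::rnorm(40, 10, 3), b = stats::runif(40),
                   c = rep(1, 40))
  s <- stats::rnorm(40, 50, 10)
  fm <- assemble_feature_matrix(df, s, c("a", "b"))
  expect_lt(max(abs(colMeans(fm$Z))), 1e-8)
  expect_equal(unname(apply(fm$Z, 2, stats::sd)), c(1, 1))

  # training constants applied to held-out data give nonzero means
  df2 <- data.frame(a = stats::rnorm(40, 14, 3), b = stats::runif(40))
  Z2 <- apply_feature_normalization(fm, df2)
  expect_gt(abs(mean(Z2[, "a"])), 0.5)
  # idempotent re-application to the training data
  expect_equal(apply_feature_normalization(fm, df), fm$Z)

  expect_error(assemble_feature_matrix(df, s, c("a", "c")),
               "zero-variance column 'c'")
  expect_error(assemble_feature_matrix(df, s, "nope"),
               "missing feature columns")

  # history columns are ruled out of estimation sets
  df$days_post_stroke <- stats::rnorm(40, 300, 50)
  fm2 <- assemble_feature_matrix(df, s, c("a", "days_post_stroke"))
  expect_identical(fm2$columns, "a")
})

test_that("log columns with non-positive values use the shift rule", {
  df <- data.frame(difficulty = c(-0.16, 0.2, 0.5, 0.89, 0.4),
                   Log.difficulty = NA_real_)
  s <- c(10, 20, 30, 40, 50)
  expect_warning(fm <- assemble_feature_matrix(df, s,
                                               c("Log.difficulty")),
                 "shifted log")
  expect_false(anyNA(fm$Z))
  expect_equal(unname(fm$log_shifts["Log.difficulty"]), -0.16 - 1e-6)
})

test_that("permutation_threshold recovers the null correlation scale", {
  set.seed(6)
  Z <- matrix(stats::rnorm(54 * 8), 54, 8)
  s <- stats::rnorm(54)
  th <- permutation_threshold(Z, s, n_perm = 400, seed = 10)
  # null SD of r is ~ 1/sqrt(n-1) = 0.137 for n = 54
  expect_lt(abs(th$null_sd - 1 / sqrt(53)), 0.01)
  # quantile 1 returns the maximum of the null distribution
  th1 <- permutation_threshold(Z, s, n_perm = 200, quantile = 1,
                               seed = 11)
  expect_gte(th1$threshold, th1$null_sd)
  # determinism under a fixed seed
  th2 <- permutation_threshold(Z, s, n_perm = 400, seed = 10)
  expect_identical(th$threshold, th2$threshold)
  expect_error(permutation_threshold(Z[1:5, ], s[1:5], 400), "10 samples")
  expect_error(permutation_threshold(Z, s, n_perm = 10), "100 permutations")
})

test_that("feature extraction is deterministic", {
  cfg <- simulation_config(session_duration = 300, seed = 2)
  p <- simulate_trajectory(0.6, cfg, seed = 5)
  f1 <- extract_hand_features(p, trim = TRUE)
  f2 <- extract_hand_features(p, trim = TRUE)
  expect_identical(f1, f2)
})
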