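#' Median-split classification accuracy
#'
#' Fraction of samples whose predicted score falls on the same side of
#' a reference median as the true score.  Values exactly equal to the
#' median count as "not above" on both sides, so a prediction equal to
#' the median agrees with a true score equal to the median.
#'
#' @param true,predicted Numeric vectors of equal length.
#' @param median_value Reference median (typically of the training
#'   scores).
#' @return Accuracy in \[0, 1\].
#' @export
median_split_accuracy <- function(true, predicted, median_value) {
  stopifnot(length(true) == length(predicted), length(true) >= 1L)
  mean((true > median_value) == (predicted > median_value))
}

#' Accuracy and error metrics for score estimation
#'
#' Reports the average error (RMSE), the Pearson correlation between
#' true and predicted scores, and the coefficient of determination
#' `R^2 = 1 - MSE / Var(true)` with the population variance, so that
#' predicting the mean of the true scores gives exactly `R^2 = 0` and
#' poor models can score negative.
#'
#' @param true,predicted Numeric vectors, length >= 2; `true` must not
#'   be constant.
#' @return List of class `performance_report` with `rmse`,
#'   `pearson_r`, `r_squared`.
#' @export
performance_metrics <- function(true, predicted) {
  stopifnot(length(true) == length(predicted), length(true) >= 2L)
  if (stats::sd(true) == 0)
    stop("constant true scores: metrics undefined", call. = FALSE)
  mse <- mean((true - predicted)^2)
  v <- mean((true - mean(true))^2)
  r <- if (stats::sd(predicted) == 0) NA_real_
       else stats::cor(true, predicted)
  structure(list(rmse = sqrt(mse), pearson_r = r,
                 r_squared = 1 - mse / v),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> rmse=%.3f, r=%.3f, R2=%.3f\n",
              x$rmse, x$pearson_r, x$r_squared))
  invisible(x)
}

#' Intraclass correlation between test and retest estimates
#'
#' Two-way random effects, absolute agreement, single measurement --
#' ICC(2,1) -- computed from the mean squares of the subject-by-rater
#' decomposition.  A consistency variant ICC(3,1) is available.
#'
#' @param test,retest Paired numeric vectors (one pair per subject),
#'   length >= 3.
#' @param type `"ICC2"` (absolute agreement, default) or `"ICC3"`
#'   (consistency).
#' @return ICC value in \[-1, 1\].
#' @export
icc_agreement <- function(test, retest, type = c("ICC2", "ICC3")) {
  type <- match.arg(type)
  stopifnot(length(test) == length(retest), length(test) >= 3L)
  x <- cbind(test, retest)
  n <- nrow(x); k <- 2L
  grand <- mean(x)
  rm_ <- rowMeans(x); cm_ <- colMeans(x)
  if (stats::var(rm_) == 0)
    stop("zero between-subject variance: ICC undefined", call. = FALSE)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  resid <- x - outer(rm_, rep(1, k)) -
    matrix(cm_, n, k, byrow = TRUE) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  if (type == "ICC2")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (k - 1) * mse)
}

#' Retest error and minimal detectable change
#'
#' The retest error is the root-mean-square difference between paired
#' test and retest estimates, `sqrt(sum_i (S_i^test - S_i^retest)^2 /
#' N)`.  The 95% minimal detectable change uses the standard error of
#' measurement `SEM = retest_error / sqrt(2)`:
#' `MDC95 = 1.96 * sqrt(2) * SEM`, which equals `1.96 *
#' retest_error` (e.g. a retest error of 5.9 score points gives an
#' MDC of 11.6 points).
#'
#' @param test,retest Paired numeric vectors of estimates.
#' @return `retest_error()`: RMS difference in score points.
#' @export
retest_error <- function(test, retest) {
  stopifnot(length(test) == length(retest), length(test) >= 1L)
  sqrt(mean((test - retest)^2))
}

#' @rdname retest_error
#' @param error A retest error in score points.
#' @return `mdc95()`: minimal detectable change in score points.
#' @export
mdc95 <- function(error) {
  stopifnot(error >= 0)
  sem <- error / sqrt(2)
  1.96 * sqrt(2) * sem
}

#' Agreement report for test-retest pairs
#'
#' @inheritParams icc_agreement
#' @return List of class `agreement_report` with `icc`,
#'   `retest_error`, `mdc`.
#' @export
agreement_report <- function(test, retest, type = "ICC2") {
  err <- retest_error(test, retest)
  structure(list(icc = icc_agreement(test, retest, type),
                 retest_error = err, mdc = mdc95(err)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> ICC=%.3f, retest error=%.2f, MDC=%.2f\n",
              x$icc, x$retest_error, x$mdc))
  invisible(x)
}

#' Sensitivity to clinically relevant recovery
#'
#' True positive rate for detecting clinically relevant change: of the
#' samples whose true score change reaches the clinical minimal
#' detectable change (default 4 points for FM-UE), the fraction whose
#' predicted change also reaches it.
#'
#' @param true_deltas,predicted_deltas Paired score changes.
#' @param clinical_mdc Change threshold in score points (default 4).
#' @return List of class `recovery_report` with `tpr`, `eligible`,
#'   `detected`, `mdc_threshold`.
#' @export
sensitivity_tpr <- function(true_deltas, predicted_deltas,
                            clinical_mdc = 4) {
  stopifnot(length(true_deltas) == length(predicted_deltas))
  eligible <- true_deltas >= clinical_mdc
  if (!any(eligible))
    stop("no samples reach the clinical MDC: TPR undefined", call. = FALSE)
  detected <- eligible & predicted_deltas >= clinical_mdc
  structure(list(tpr = sum(detected) / sum(eligible),
                 eligible = sum(eligible), detected = sum(detected),
                 mdc_threshold = clinical_mdc),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> TPR=%.3f (%d of %d above %g points)\n",
              x$tpr, x$detected, x$eligible, x$mdc_threshold))
  invisible(x)
}

#' Cross-scale rescaling benchmark
#'
#' Benchmark accuracy obtained by estimating one clinical scale from
#' another by a fixed rescaling factor, e.g. FM-UE from CAHAI with
#' factor 66/91 or FM-UE from BI with factor 66/100.  These benchmarks
#' bracket what a kinematics-based estimator should achieve.
#'
#' @param target_scores True scores on the target scale.
#' @param source_scores Paired scores on the source scale.
#' @param factor Rescaling factor applied to the source scores.
#' @return [performance_metrics()] report of the rescaled predictions.
#' @export
rescaling_benchmark <- function(target_scores, source_scores, factor) {
  performance_metrics(target_scores, factor * source_scores)
}

#' Canonical rescaling factors between the supported scales
#' @return Named list of factors onto the FM-UE range.
#' @export
rescaling_factors <- function() {
  list(cahai_to_fm_ue = 66 / 91, bi_to_fm_ue = 66 / 100)
}

default_model_config <- function(config = list()) {
  utils::modifyList(list(variant = "covariate", prior = prior_config(),
                         n_starts = 4, nodes = 32), config)
}

cv_fit_predict <- function(Ztr, Str, Zva, config) {
  # normalize with training constants only
  ctr <- colMeans(Ztr)
  sc <- apply(Ztr, 2L, stats::sd)
  if (any(sc == 0)) stop("zero-variance training column", call. = FALSE)
  norm <- function(M) sweep(sweep(M, 2L, ctr), 2L, sc, "/")
  Ztr_n <- norm(Ztr)
  Zva_n <- if (nrow(Zva)) norm(Zva) else Zva
  fit <- if (config$variant == "linear") {
    fit_linear_baseline(Ztr_n, Str, prior = config$prior,
                        compute_errors = FALSE)
  } else {
    fit_noise_model(Ztr_n, Str, variant = config$variant,
                    prior = config$prior, n_starts = config$n_starts,
                    seed = config$fit_seed, nodes = config$nodes,
                    compute_errors = FALSE)
  }
  list(pred_tr = predict(fit, Ztr_n),
       pred_va = if (nrow(Zva)) predict(fit, Zva_n) else numeric(0),
       fit = fit)
}

#' Repeated split-half cross-validation
#'
#' For each repeat, the samples are split at random into a training
#' and a validation half (default 50/50); the model is fitted on the
#' training half (with normalization constants computed from the
#' training half only), and the median-split accuracy is evaluated on
#' both halves using the training-set median.  Failed fits are
#' recorded and excluded from the means, with a warning when more than
#' 10% fail.
#'
#' @param covariates Raw (unnormalized) covariate matrix or data
#'   frame, n x p.
#' @param scores Numeric score vector of length n.
#' @param model_config List with `variant` (`"covariate"`, `"score"`,
#'   `"double"` or `"linear"`), `prior`, `n_starts`, `nodes`.
#' @param n_repeats Number of random splits (default 50).
#' @param split Training fraction (default 0.5).
#' @param seed Optional integer seed; fixes the whole procedure.
#' @return List of class `crossval_report` with per-repeat accuracies
#'   and their means.
#' @export
repeated_cv <- function(covariates, scores, model_config = list(),
                        n_repeats = 50, split = 0.5, seed = NULL) {
  Z <- as.matrix(covariates)
  n <- nrow(Z)
  if (n < 10L) stop("need at least 10 samples", call. = FALSE)
  config <- default_model_config(model_config)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  acc_tr <- acc_va <- rep(NA_real_, n_repeats)
  failures <- 0L
  for (r in seq_len(n_repeats)) {
    idx <- sample.int(n, floor(n * split))
    config$fit_seed <- if (is.null(seed)) NULL else seed + r
    res <- tryCatch(
      cv_fit_predict(Z[idx, , drop = FALSE], scores[idx],
                     Z[-idx, , drop = FALSE], config),
      error = function(e) NULL)
    if (is.null(res)) { failures <- failures + 1L; next }
    med <- stats::median(scores[idx])
    acc_tr[r] <- median_split_accuracy(scores[idx], res$pred_tr, med)
    acc_va[r] <- median_split_accuracy(scores[-idx], res$pred_va, med)
  }
  if (failures > 0.1 * n_repeats)
    warning(sprintf("%d of %d cross-validation fits failed",
                    failures, n_repeats))
  structure(list(train_accuracy = acc_tr, validation_accuracy = acc_va,
                 mean_train_accuracy = mean(acc_tr, na.rm = TRUE),
                 mean_validation_accuracy = mean(acc_va, na.rm = TRUE),
                 split = split, n_repeats = n_repeats,
                 failures = failures, seed = seed,
                 variant = config$variant),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf(paste0("<crossval_report> %d repeats (%g/%g split): ",
                     "train %.3f, validation %.3f\n"),
              x$n_repeats, x$split, 1 - x$split,
              x$mean_train_accuracy, x$mean_validation_accuracy))
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' Performs `n` fits, each leaving one sample out; the held-out sample
#' is classified against the median of its training set.  Reports the
#' held-out (validation) accuracy and the mean training accuracy
#' across fits.
#'
#' @inheritParams repeated_cv
#' @return List with `train_accuracy`, `validation_accuracy`,
#'   `n_fits`.
#' @export
loocv <- function(covariates, scores, model_config = list(), seed = NULL) {
  Z <- as.matrix(covariates)
  n <- nrow(Z)
  if (n < 10L) stop("need at least 10 samples", call. = FALSE)
  config <- default_model_config(model_config)
  correct <- rep(NA, n)
  acc_tr <- rep(NA_real_, n)
  failures <- 0L
  for (i in seq_len(n)) {
    config$fit_seed <- if (is.null(seed)) NULL else seed + i
    res <- tryCatch(
      cv_fit_predict(Z[-i, , drop = FALSE], scores[-i],
                     Z[i, , drop = FALSE], config),
      error = function(e) NULL)
    if (is.null(res)) { failures <- failures + 1L; next }
    med <- stats::median(scores[-i])
    acc_tr[i] <- median_split_accuracy(scores[-i], res$pred_tr, med)
    correct[i] <- (scores[i] > med) == (res$pred_va > med)
  }
  if (failures > 0.1 * n)
    warning(sprintf("%d of %d leave-one-out fits failed", failures, n))
  list(train_accuracy = mean(acc_tr, na.rm = TRUE),
       validation_accuracy = mean(correct, na.rm = TRUE),
       n_fits = n, failures = failures)
}

#' Greedy forward selection of the active variable set
#'
#' Starting from a forced set of covariates, repeatedly adds the
#' candidate that most improves the mean validation accuracy under
#' repeated split-half cross-validation, stopping when no candidate
#' improves the accuracy by more than `improvement_tol`.  Ties are
#' broken toward the smaller set, then by lexicographic column order.
#'
#' @param covariates Raw covariate matrix or data frame with named
#'   columns.
#' @param scores Score vector.
#' @param candidates Character vector of candidate column names.
#' @param forced Character vector of columns always kept (must be a
#'   subset of the available columns).
#' @param cv_config List passed to [repeated_cv()]: `model_config`,
#'   `n_repeats`, `split`.
#' @param improvement_tol Minimum accuracy gain to accept an addition
#'   (default 0.002).
#' @param seed Integer seed making the whole selection deterministic.
#' @return List with `active` (selected column names) and `trace`
#'   (data frame of steps).
#' @export
select_active_variables <- function(covariates, scores, candidates,
                                    forced = character(),
                                    cv_config = list(),
                                    improvement_tol = 0.002,
                                    seed = NULL) {
  covariates <- as.data.frame(covariates)
  if (!length(candidates) && !length(forced))
    stop("no candidates and no forced variables", call. = FALSE)
  bad <- setdiff(c(candidates, forced), names(covariates))
  if (length(bad))
    stop("unknown columns: ", paste(bad, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(list(model_config = list(), n_repeats = 10,
                                split = 0.5), cv_config)
  eval_set <- function(set, step) {
    if (!length(set)) return(-Inf)
    rep <- repeated_cv(covariates[, set, drop = FALSE], scores,
                       model_config = cfg$model_config,
                       n_repeats = cfg$n_repeats, split = cfg$split,
                       seed = if (is.null(seed)) NULL else seed + step)
    rep$mean_validation_accuracy
  }
  active <- sort(unique(forced))
  step <- 0L
  current_acc <- eval_set(active, step)
  trace <- data.frame(step = integer(), added = character(),
                      accuracy = numeric())
  remaining <- sort(setdiff(candidates, active))
  while (length(remaining)) {
    step <- step + 1L
    accs <- vapply(remaining, function(cand)
      eval_set(c(active, cand), step), numeric(1))
    best <- max(accs)
    if (!is.finite(best) ||
        (is.finite(current_acc) && best <= current_acc + improvement_tol))
      break
    pick <- remaining[which(accs == best)][1L] # lexicographic tie-break
    active <- sort(c(active, pick))
    trace <- rbind(trace, data.frame(step = step, added = pick,
                                     accuracy = best))
    current_acc <- best
    remaining <- setdiff(remaining, pick)
  }
  list(active = active, trace = trace, accuracy = current_acc)
}
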