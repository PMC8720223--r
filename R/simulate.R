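#' Configuration for the synthetic session generator
#'
#' Bundles the generator's study conditions: session length and
#' sampling (30-minute sessions at 100 Hz), target spheres launched
#' every ~10 s, reach amplitudes scaled by the patient's latent
#' function level, high-frequency jitter scaled by impairment, an
#' adaptive difficulty controller holding success near 70-80%, and the
#' generative score model used to assign clinical scores to simulated
#' sessions.
#'
#' @param n_patients Number of patients in a cohort.
#' @param sessions_per_patient Sessions generated per patient.
#' @param session_duration Session length in seconds (default 1800).
#' @param sample_step Sampling step in seconds (default 0.01).
#' @param event_interval Mean inter-target interval in seconds
#'   (default 10).
#' @param base_reach Maximum lateral target offset in metres.
#' @param reach_duration Base reach duration in seconds.
#' @param jitter_amp High-frequency jitter amplitude (m) at full
#'   impairment.
#' @param jitter_band Jitter band in Hz (band-limited Gaussian noise).
#' @param difficulty_step Controller difficulty increment.
#' @param difficulty_window Trailing event window for the controller.
#' @param theta [noise_model_params] of the generative score model
#'   applied to normalized cohort covariates.
#' @param score_covariates Feature columns entering the score model.
#' @param sigma_low,sigma_high Descriptor timescales used when
#'   extracting cohort features.
#' @param seed Integer seed; all cohort randomness flows from it.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 20,
                              sessions_per_patient = 1,
                              session_duration = 1800,
                              sample_step = 0.01,
                              event_interval = 10,
                              base_reach = 0.35,
                              reach_duration = 1.2,
                              jitter_amp = 0.012,
                              jitter_band = c(2, 8),
                              difficulty_step = 0.02,
                              difficulty_window = 10,
                              theta = NULL,
                              score_covariates = c("tgdm", "smoothness",
                                                   "difficulty"),
                              sigma_low = 8.8,
                              sigma_high = 0.01,
                              seed = 1L) {
  if (is.null(theta))
    theta <- noise_model_params(beta = c(0.9, -0.25, 0.3), beta0 = 0.2,
                                A = 4, B = 66, sigma1 = 0.5, sigma2 = 0)
  stopifnot(session_duration > 0, sample_step > 0, event_interval > 0,
            length(theta$beta) == length(score_covariates))
  structure(list(n_patients = n_patients,
                 sessions_per_patient = sessions_per_patient,
                 session_duration = session_duration,
                 sample_step = sample_step,
                 event_interval = event_interval,
                 base_reach = base_reach, reach_duration = reach_duration,
                 jitter_amp = jitter_amp, jitter_band = jitter_band,
                 difficulty_step = difficulty_step,
                 difficulty_window = difficulty_window,
                 theta = theta, score_covariates = score_covariates,
                 sigma_low = sigma_low, sigma_high = sigma_high,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

min_jerk <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

event_schedule <- function(config, duration) {
  # targets launched every ~event_interval s with +-20% jitter
  gaps <- config$event_interval * stats::runif(
    ceiling(duration / config$event_interval * 1.6) + 4L, 0.8, 1.2)
  times <- cumsum(gaps)
  times[times < duration - config$event_interval / 2]
}

band_limited_jitter <- function(n, fs, band) {
  ny <- fs / 2
  bf <- signal::butter(2, pmin(band / ny, 0.99), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

#' Simulate one hand's trajectory
#'
#' Emulates goal-directed horizontal reaching during a target-
#' interception session: targets appear every ~10 s at lateral offsets,
#' the hand performs a minimum-jerk reach toward each target with
#' amplitude scaled by the latent function level, and band-limited
#' Gaussian jitter (2-8 Hz) with amplitude scaled by impairment
#' (1 - function level) is superimposed.  A smaller frontal component
#' makes the path planar.
#'
#' @param function_level Latent arm function in \[0, 1\]
#'   (1 = least impaired).
#' @param config A [simulation_config].
#' @param seed Integer seed; the path is a pure function of
#'   (`function_level`, `config`, `seed`).
#' @param side Limb label for the returned path.
#' @param event_times Optional externally supplied target times (s).
#' @return A [hand_path].
#' @export
simulate_trajectory <- function(function_level, config = simulation_config(),
                                seed = 1L, side = "paretic",
                                event_times = NULL) {
  stopifnot(function_level >= 0, function_level <= 1)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  fs <- 1 / config$sample_step
  n <- round(config$session_duration / config$sample_step)
  times <- (seq_len(n) - 1L) * config$sample_step
  if (is.null(event_times))
    event_times <- event_schedule(config, config$session_duration)
  gain <- 0.15 + 0.85 * function_level
  dur_reach <- config$reach_duration * (1.6 - 0.6 * function_level)
  lat <- numeric(n)
  fro <- numeric(n)
  cur_l <- 0; cur_f <- 0
  last_end <- 1L
  for (te in event_times) {
    i0 <- min(n, floor(te / config$sample_step) + 1L)
    if (i0 <= last_end) i0 <- last_end + 1L
    if (i0 > n) break
    lat[last_end:i0] <- cur_l
    fro[last_end:i0] <- cur_f
    tgt_l <- sample(c(-1, 1), 1) * config$base_reach * stats::runif(1, 0.5, 1)
    tgt_f <- 0.35 * config$base_reach * stats::runif(1, -1, 1)
    end_l <- cur_l + (tgt_l - cur_l) * gain
    end_f <- cur_f + (tgt_f - cur_f) * gain
    i1 <- min(n, i0 + round(dur_reach * fs))
    if (i1 > i0) {
      tau <- (seq(i0, i1) - i0) / (i1 - i0)
      prof <- min_jerk(tau)
      lat[i0:i1] <- cur_l + (end_l - cur_l) * prof
      fro[i0:i1] <- cur_f + (end_f - cur_f) * prof
    }
    cur_l <- end_l; cur_f <- end_f
    last_end <- i1
  }
  if (last_end < n) {
    lat[last_end:n] <- cur_l
    fro[last_end:n] <- cur_f
  }
  jit <- config$jitter_amp * (1 - function_level) + 5e-4
  lat <- lat + jit * band_limited_jitter(n, fs, config$jitter_band)
  fro <- fro + 0.6 * jit * band_limited_jitter(n, fs, config$jitter_band)
  # sensor noise at sub-millimetre level
  lat <- lat + stats::rnorm(n, 0, 2e-4)
  fro <- fro + stats::rnorm(n, 0, 2e-4)
  hand_path(times, lat, frontal = fro, side = side)
}

#' Adaptive difficulty controller
#'
#' Per-target success is Bernoulli with probability
#' `plogis((ability - difficulty) / 0.15)`.  After each target, the
#' trailing-window success rate drives the difficulty: above 0.8 the
#' difficulty is raised, below 0.7 lowered, holding the long-run
#' success fraction inside the 70-80% band the task aims for.
#'
#' @param ability Latent task ability in (0, 1).
#' @param config A [simulation_config].
#' @param seed Integer seed.
#' @param n_events Number of targets to simulate.
#' @param frozen If TRUE the difficulty is never adapted.
#' @return List with `difficulty_trace` (per-event difficulty) and
#'   `events` (data frame `time`, `outcome`).
#' @export
run_difficulty_controller <- function(ability, config = simulation_config(),
                                      seed = 1L, n_events = NULL,
                                      frozen = FALSE) {
  stopifnot(ability > 0, ability < 1)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  times <- event_schedule(config, config$session_duration)
  if (!is.null(n_events)) {
    while (length(times) < n_events)
      times <- c(times, times[length(times)] +
                   config$event_interval * stats::runif(1, 0.8, 1.2))
    times <- times[seq_len(n_events)]
  }
  m <- length(times)
  scale <- 0.15
  # start at the difficulty whose success probability is mid-band (0.75)
  diff_cur <- ability - scale * log(3)
  diffs <- numeric(m)
  hits <- logical(m)
  w <- config$difficulty_window
  for (i in seq_len(m)) {
    diffs[i] <- diff_cur
    hits[i] <- stats::runif(1) < stats::plogis((ability - diff_cur) / scale)
    if (!frozen && i >= w) {
      rate <- mean(hits[(i - w + 1L):i])
      if (rate > 0.8) diff_cur <- diff_cur + config$difficulty_step
      else if (rate < 0.7) diff_cur <- diff_cur - config$difficulty_step
      diff_cur <- min(max(diff_cur, -0.3), 1.0)
    }
  }
  list(difficulty_trace = diffs,
       events = data.frame(time = times,
                           outcome = ifelse(hits, "hit", "miss")))
}

simulate_session <- function(patient, config, seed, session_index,
                             session_date) {
  ctrl <- run_difficulty_controller(min(max(patient$function_level,
                                            0.05), 0.95),
                                    config, seed = seed)
  paretic <- simulate_trajectory(patient$function_level, config,
                                 seed = seed + 1L, side = "paretic",
                                 event_times = ctrl$events$time)
  non_paretic <- simulate_trajectory(patient$np_function_level, config,
                                     seed = seed + 2L, side = "non_paretic",
                                     event_times = ctrl$events$time)
  session_record(patient$patient_id, session_index,
                 paths = list(paretic = paretic, non_paretic = non_paretic),
                 events = ctrl$events,
                 difficulty_trace = ctrl$difficulty_trace,
                 metadata = patient$metadata,
                 session_date = session_date)
}

draw_patients <- function(config) {
  n <- config$n_patients
  fl <- stats::rbeta(n, 2.2, 1.8)
  fl <- pmin(pmax(fl, 0.02), 0.98)
  np <- pmin(1, fl + (1 - fl) * stats::runif(n, 0.6, 0.9))
  lapply(seq_len(n), function(i) {
    days <- min(3045, max(5, round(stats::rlnorm(1, log(150), 1.1))))
    list(patient_id = sprintf("P%03d", i),
         function_level = fl[i], np_function_level = np[i],
         metadata = list(
           age = round(min(87, max(23, stats::rnorm(1, 63, 13)))),
           gender = stats::rbinom(1, 1, 118 / 191),
           dominant_side_affected = stats::rbinom(1, 1, 72 / 191),
           days_post_stroke = days,
           sessions_completed = 2L + stats::rpois(1, 9)))
  })
}

generative_score <- function(theta, Z) {
  n <- nrow(Z)
  u <- stats::rnorm(n); v <- stats::rnorm(n)
  eta <- as.vector(Z %*% theta$beta) + theta$beta0
  theta$a * tanh(eta + theta$sigma1 * u) + theta$b + theta$sigma2 * v
}

#' Simulate a cohort of scored sessions
#'
#' Draws latent patients (function level, demographics), simulates
#' their sessions, extracts the kinematic descriptors, and assigns
#' clinical scores from the generative bounded tanh model applied to
#' the cohort-normalized covariates:
#' `S = a tanh(beta . Z + beta_0 + sigma_1 u) + b + sigma_2 v`.
#' The non-paretic limb's function level is always at least the
#' paretic one.  Ground truth (latent levels, theta, Z, scores) is
#' recorded for validation.
#'
#' @param config A [simulation_config].
#' @return List of class `kinscore_cohort`: `sessions` (list of
#'   [session_record]), `features` (data frame), `scores`
#'   (data frame `patient_id`, `session_date`, `fm_ue`), `fm`
#'   (the cohort `feature_matrix`), `truth`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  if (config$n_patients == 0L)
    return(structure(list(sessions = list(),
                          features = NULL, scores = NULL, fm = NULL,
                          truth = NULL, config = config),
                     class = "kinscore_cohort"))
  patients <- draw_patients(config)
  sessions <- list()
  fl_of_session <- numeric(0)
  k <- 0L
  for (i in seq_along(patients)) {
    for (s in seq_len(config$sessions_per_patient)) {
      k <- k + 1L
      sessions[[k]] <- simulate_session(
        patients[[i]], config,
        seed = config$seed + 1000L + 10L * k,
        session_index = 2L + s, # past the familiarisation sessions
        session_date = 100 + 30 * (s - 1) + i %% 7)
      fl_of_session[k] <- patients[[i]]$function_level
    }
  }
  features <- do.call(rbind, lapply(sessions, extract_session_features,
                                    sigma_low = config$sigma_low,
                                    sigma_high = config$sigma_high))
  fm <- assemble_feature_matrix(features,
                                scores = rep(0, nrow(features)),
                                columns = config$score_covariates)
  scores <- generative_score(config$theta, fm$Z)
  fm$S <- scores
  score_table <- data.frame(
    patient_id = features$patient_id,
    assessment_date = vapply(sessions, function(s) s$session_date,
                             numeric(1)),
    fm_ue = scores)
  structure(list(sessions = sessions, features = features,
                 scores = score_table, fm = fm,
                 truth = list(function_levels = fl_of_session,
                              patients = patients,
                              theta = config$theta, Z = fm$Z,
                              scores = scores),
                 config = config),
            class = "kinscore_cohort")
}

#' @export
print.kinscore_cohort <- function(x, ...) {
  cat(sprintf("<kinscore_cohort> %d sessions from %d patients\n",
              length(x$sessions), x$config$n_patients))
  invisible(x)
}

#' Simulate test-retest session pairs
#'
#' For each patient of a cohort, generates two sessions less than 48 h
#' apart with an identical latent function level (only the noise draws
#' differ), emulating repeated measurements of an unchanged clinical
#' state.
#'
#' @param cohort A `kinscore_cohort`.
#' @param seed Integer seed.
#' @return List of pairs; each pair is a list with `test` and
#'   `retest` [session_record]s and the shared `function_level`.
#' @export
simulate_retest_pairs <- function(cohort, seed = NULL) {
  stopifnot(inherits(cohort, "kinscore_cohort"))
  config <- cohort$config
  if (is.null(seed)) seed <- config$seed + 5e5L
  patients <- cohort$truth$patients
  lapply(seq_along(patients), function(i) {
    p <- patients[[i]]
    d0 <- 200 + i
    list(test = simulate_session(p, config, seed = seed + 10L * i,
                                 session_index = 10L, session_date = d0),
         retest = simulate_session(p, config, seed = seed + 10L * i + 5L,
                                   session_index = 11L,
                                   session_date = d0 + 1),
         function_level = p$function_level)
  })
}

#' Simulate recovery session pairs with planted improvement
#'
#' For each patient, a baseline session and a follow-up more than 16
#' days later are generated; the follow-up function level is advanced
#' by a truncated-normal improvement (default mean 0.1 on the latent
#' scale).  Scores for both sessions come from the cohort's generative
#' model using the cohort normalization constants, and the true score
#' changes are recorded.
#'
#' @param cohort A `kinscore_cohort`.
#' @param improvement List with `mean` and `sd` of the latent
#'   improvement (truncated at 0).
#' @param seed Integer seed.
#' @return List with `pairs` (baseline/followup records), `deltas`
#'   (true score changes), `scores` (per-session scores) and
#'   `function_levels`.
#' @export
simulate_recovery_pairs <- function(cohort,
                                    improvement = list(mean = 0.1,
                                                       sd = 0.05),
                                    seed = NULL) {
  stopifnot(inherits(cohort, "kinscore_cohort"))
  config <- cohort$config
  if (is.null(seed)) seed <- config$seed + 7e5L
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  patients <- cohort$truth$patients
  gaps <- round(stats::runif(length(patients), 17, 90))
  incs <- pmax(0, stats::rnorm(length(patients), improvement$mean,
                               improvement$sd))
  pairs <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    p0 <- patients[[i]]
    p1 <- p0
    p1$function_level <- min(1, p0$function_level + incs[i])
    p1$np_function_level <- max(p1$np_function_level, p1$function_level)
    d0 <- 300 + i
    pairs[[i]] <- list(
      baseline = simulate_session(p0, config, seed = seed + 20L * i,
                                  session_index = 12L, session_date = d0),
      followup = simulate_session(p1, config, seed = seed + 20L * i + 7L,
                                  session_index = 13L,
                                  session_date = d0 + gaps[i]),
      improvement = incs[i], gap_days = gaps[i])
  }
  feats <- do.call(rbind, lapply(pairs, function(pr) rbind(
    extract_session_features(pr$baseline, sigma_low = config$sigma_low,
                             sigma_high = config$sigma_high),
    extract_session_features(pr$followup, sigma_low = config$sigma_low,
                             sigma_high = config$sigma_high))))
  Z <- apply_feature_normalization(cohort$fm, feats)
  S <- generative_score(config$theta, Z)
  idx0 <- seq(1, by = 2, length.out = length(pairs))
  list(pairs = pairs, features = feats, scores = S,
       deltas = S[idx0 + 1] - S[idx0],
       function_levels = cbind(
         baseline = vapply(patients, `[[`, numeric(1), "function_level"),
         followup = pmin(1, vapply(patients, `[[`, numeric(1),
                                   "function_level") + incs)))
}
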