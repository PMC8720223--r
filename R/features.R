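#' Work area: convex hull of the planar hand positions
#'
#' Area (m^2) of the convex hull of the 2-D point cloud visited by the
#' hand, computed by gift wrapping (Jarvis march).  Degenerate clouds
#' (fewer than 3 distinct points, or all collinear) have area 0.
#'
#' @param path A [hand_path] with both axes present.
#' @return Hull area in m^2.
#' @export
work_area <- function(path) {
  stopifnot(inherits(path, "hand_path"))
  if (is.null(path$frontal))
    stop("work area requires 2-D data", call. = FALSE)
  hull <- jarvis_hull(path$lateral, path$frontal)
  if (length(hull) < 3L) return(0)
  polygon_area(path$lateral[hull], path$frontal[hull])
}

# Gift-wrapping (Jarvis march): walk the hull counterclockwise, at each
# vertex picking the point with the smallest positive turn from the
# incoming direction (farthest point on angle ties, so collinear
# boundary points are skipped).  Returns indices into (x, y).
jarvis_hull <- function(x, y) {
  keep <- !duplicated(cbind(x, y))
  idx <- which(keep)
  xs <- x[idx]; ys <- y[idx]
  m <- length(xs)
  if (m < 3L) return(idx)
  start <- order(ys, xs)[1L]
  hull <- integer(0)
  cur <- start
  prev_ang <- 0 # incoming direction: start pointing along +x
  repeat {
    hull <- c(hull, cur)
    dx <- xs - xs[cur]; dy <- ys - ys[cur]
    ang <- atan2(dy, dx)
    rel <- (ang - prev_ang) %% (2 * pi)
    rel[cur] <- Inf
    # smallest turn; on ties take the farthest point
    d2 <- dx^2 + dy^2
    best <- which(abs(rel - min(rel)) < 1e-12)
    nxt <- best[which.max(d2[best])]
    prev_ang <- ang[nxt]
    if (nxt == start || length(hull) > m) break
    cur <- nxt
  }
  idx[hull]
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Total distance covered by the hand (m)
#'
#' Sum of the Euclidean lengths of consecutive trajectory segments,
#' using both axes when present.
#'
#' @param path A [hand_path].
#' @return Path length in metres.
#' @export
distance_covered <- function(path) {
  stopifnot(inherits(path, "hand_path"))
  dx <- diff(path$lateral)
  if (is.null(path$frontal)) return(sum(abs(dx)))
  sum(sqrt(dx^2 + diff(path$frontal)^2))
}

#' Maximum reaching speed (m/s)
#'
#' Maximum over consecutive samples of segment length divided by time
#' step, computed on raw samples with no pre-filtering, so single-sample
#' glitches are retained as in the raw session logs.
#'
#' @param path A [hand_path].
#' @param axis Optional single axis; by default the 2-D (or available)
#'   segment length is used.
#' @return Maximum finite-difference speed in m/s.
#' @export
max_reaching_speed <- function(path, axis = NULL) {
  stopifnot(inherits(path, "hand_path"))
  dt <- diff(path$times)
  if (any(dt == 0))
    stop("repeated timestamps: speed undefined", call. = FALSE)
  max(segment_lengths(path, axis) / dt)
}

segment_lengths <- function(path, axis = NULL) {
  if (!is.null(axis)) return(abs(diff(path_axis(path, axis))))
  dx <- diff(path$lateral)
  if (is.null(path$frontal)) abs(dx) else sqrt(dx^2 + diff(path$frontal)^2)
}

#' Task performance: fraction of targets intercepted
#'
#' @param events Data frame with an `outcome` column of `"hit"`/`"miss"`
#'   tokens (as stored in a [session_record]).
#' @return Hit fraction in \[0, 1\].
#' @export
performance_rate <- function(events) {
  if (is.null(events) || nrow(events) == 0L)
    stop("no targets: performance undefined", call. = FALSE)
  mean(events$outcome == "hit")
}

#' Windowed movement range and speed descriptors
#'
#' Comparison descriptors computed over maximally overlapping time
#' windows slid sample-by-sample along the session:
#' `windowed_max_range` takes the position range (max - min) on one axis
#' per window and averages across windows; `windowed_max_speed` does the
#' same with the maximum finite-difference speed per window.  When the
#' session is shorter than the window, a single whole-session window is
#' used and a warning is emitted.
#'
#' @param path A trimmed [hand_path].
#' @param axis Axis for the range descriptor.
#' @param window_s Window length in seconds (64 s for the range
#'   descriptor, 14 s for the speed descriptor).
#' @return Average of the per-window maxima, in m or m/s.
#' @export
windowed_max_range <- function(path, axis = c("lateral", "frontal"),
                               window_s = 64) {
  axis <- match.arg(axis)
  v <- path_axis(path, axis)
  k <- window_samples(path$times, window_s)
  if (is.na(k)) {
    warning("session shorter than window; using a single whole-session window")
    return(diff(range(v)))
  }
  mean(zoo::rollmax(v, k) + zoo::rollmax(-v, k))
}

#' @rdname windowed_max_range
#' @export
windowed_max_speed <- function(path, window_s = 14) {
  dt <- diff(path$times)
  if (any(dt == 0))
    stop("repeated timestamps: speed undefined", call. = FALSE)
  sp <- segment_lengths(path) / dt
  k <- window_samples(path$times[-1], window_s)
  if (is.na(k)) {
    warning("session shorter than window; using a single whole-session window")
    return(max(sp))
  }
  mean(zoo::rollmax(sp, k))
}

window_samples <- function(times, window_s) {
  dur <- times[length(times)] - times[1]
  if (dur < window_s) return(NA_integer_)
  k <- floor(window_s / mean(diff(times))) + 1L
  min(k, length(times))
}

#' Extract the per-session kinematic descriptors for one hand
#'
#' @param path A [hand_path] (untrimmed; trimming is applied here).
#' @param events,difficulty_trace Task events and difficulty samples of
#'   the session.
#' @param sigma_low,sigma_high TGDM and Smoothness timescales (s).
#' @param trim Apply [trim_session()] first (default TRUE).
#' @param windowed Also compute the windowed comparison descriptors
#'   (slower; default FALSE).
#' @param two_axis Also compute the frontal-axis TGDM (for tasks using
#'   the full plane).
#' @return Named list of descriptors (a `kinematic_features` record).
#' @export
extract_hand_features <- function(path, events = NULL,
                                  difficulty_trace = NULL,
                                  sigma_low = 8.8, sigma_high = 0.01,
                                  trim = TRUE, windowed = FALSE,
                                  two_axis = !is.null(path$frontal)) {
  p <- if (trim) trim_session(path) else path
  out <- list(
    work_area = if (is.null(p$frontal)) NA_real_ else work_area(p),
    distance_covered = distance_covered(p),
    max_reaching_speed = max_reaching_speed(p),
    smoothness = extract_smoothness(p, sigma_high),
    tgdm = extract_tgdm(p, "lateral", sigma_low)
  )
  if (two_axis) out$tgdm_fb <- extract_tgdm(p, "frontal", sigma_low)
  if (!is.null(events)) out$performance <- performance_rate(events)
  if (!is.null(difficulty_trace) && length(difficulty_trace))
    out$difficulty <- mean(difficulty_trace)
  if (windowed) {
    out$windowed_max_range <- windowed_max_range(p, window_s = 64)
    out$windowed_max_speed <- windowed_max_speed(p, window_s = 14)
  }
  out
}

#' Chronicity category from days post-stroke
#'
#' @param days_post_stroke Days since the stroke event.
#' @param cutoffs Two cut points (days): below the first is `"acute"`,
#'   between them `"subacute"`, above the second `"chronic"`.
#' @return Character category.
#' @export
chronicity_category <- function(days_post_stroke, cutoffs = c(30, 180)) {
  stopifnot(length(cutoffs) == 2L, cutoffs[1] < cutoffs[2])
  ifelse(days_post_stroke < cutoffs[1], "acute",
         ifelse(days_post_stroke <= cutoffs[2], "subacute", "chronic"))
}

#' Second-order descriptors: interlimb differences, logs, chronicity
#'
#' Builds the derived covariates from the two limbs' descriptor sets:
#' `Diff.x = x(non-paretic) - x(paretic)` for each limb-specific
#' quantitative descriptor, `Log.x = log(x)` of positive paretic-limb
#' descriptors (non-positive values yield `NA` with a warning; a
#' train-set shift rule is applied later at matrix assembly), and the
#' chronicity category.
#'
#' @param paretic,non_paretic Descriptor lists from
#'   [extract_hand_features()] for the two limbs of the same session.
#' @param metadata Session metadata list (needs `days_post_stroke`).
#' @return Named list of second-order descriptors.
#' @export
second_order_features <- function(paretic, non_paretic, metadata = list()) {
  limb_vars <- intersect(names(paretic), names(non_paretic))
  limb_vars <- limb_vars[vapply(paretic[limb_vars], is.numeric, logical(1))]
  limb_vars <- setdiff(limb_vars, c("performance", "difficulty"))
  out <- list()
  for (v in limb_vars) {
    pv <- paretic[[v]]; nv <- non_paretic[[v]]
    out[[paste0("Diff.", v)]] <-
      if (is.na(pv) || is.na(nv)) NA_real_ else nv - pv
  }
  log_vars <- c(limb_vars, intersect(c("performance", "difficulty"),
                                     names(paretic)))
  for (v in log_vars) {
    pv <- paretic[[v]]
    if (is.na(pv)) { out[[paste0("Log.", v)]] <- NA_real_; next }
    if (pv <= 0) {
      warning(sprintf("log of non-positive '%s'; deferring to shift rule", v))
      out[[paste0("Log.", v)]] <- NA_real_
    } else out[[paste0("Log.", v)]] <- log(pv)
  }
  if (!is.null(metadata$days_post_stroke))
    out$chronicity <- chronicity_category(metadata$days_post_stroke)
  out
}

#' Extract the full feature row for one session
#'
#' Combines baseline characteristics, paretic-limb first-order
#' descriptors and second-order descriptors into one named row.
#'
#' @param record A [session_record].
#' @inheritParams extract_hand_features
#' @return One-row data frame of features.
#' @export
extract_session_features <- function(record, sigma_low = 8.8,
                                     sigma_high = 0.01, windowed = FALSE) {
  stopifnot(inherits(record, "session_record"))
  md <- record$metadata
  fp <- extract_hand_features(record$paths$paretic, record$events,
                              record$difficulty_trace,
                              sigma_low = sigma_low, sigma_high = sigma_high,
                              windowed = windowed)
  fn <- extract_hand_features(record$paths$non_paretic,
                              sigma_low = sigma_low, sigma_high = sigma_high)
  so <- suppressWarnings(second_order_features(fp, fn, md))
  base <- list(patient_id = record$patient_id,
               session_index = record$session_index,
               age = md$age %||% NA_real_,
               gender = md$gender %||% NA_real_,
               dominant_side_affected = md$dominant_side_affected %||% NA_real_,
               days_post_stroke = md$days_post_stroke %||% NA_real_,
               sessions_completed = md$sessions_completed %||% NA_real_)
  row <- c(base, fp, so)
  as.data.frame(row, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Feature-table columns excluded from score estimation
#'
#' Score estimation is meant to assess the clinical status at a given
#' moment without knowledge of the rehabilitation history, so time
#' since stroke, sessions completed and functions of them are ruled
#' out of the candidate covariates.
#' @return Character vector of column names.
#' @export
history_columns <- function() {
  c("days_post_stroke", "sessions_completed", "chronicity",
    "Log.days_post_stroke", "Log.sessions_completed")
}

#' Assemble a normalized feature matrix with scores
#'
#' Z-normalizes each quantitative column (centre = mean, scale = SD of
#' the assembly set) and stores the constants so that held-out data can
#' be normalized with training-set constants.  Columns tagged for log
#' transform that contain non-positive values are shifted by
#' `x - min_train + 1e-6` before the log; the shift is stored.  The
#' chronicity category is dummy-coded (subacute/chronic indicators,
#' acute as reference) and left unscaled.
#'
#' @param features Data frame from [extract_session_features()] rows.
#' @param scores Numeric score vector, one per row of `features`.
#' @param columns Character vector of feature columns to include.
#' @param exclude_history Drop the rehabilitation-history columns
#'   ([history_columns()]) even if requested (default TRUE).
#' @return An object of class `feature_matrix`: list with `Z` (n x p
#'   normalized matrix), `S`, `columns`, `centers`, `scales`,
#'   `log_shifts`.
#' @export
assemble_feature_matrix <- function(features, scores, columns,
                                    exclude_history = TRUE) {
  stopifnot(nrow(features) == length(scores))
  if (exclude_history) columns <- setdiff(columns, history_columns())
  missing_cols <- setdiff(columns, names(features))
  if (length(missing_cols))
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  cols <- list(); centers <- c(); scales <- c(); shifts <- c()
  for (nm in columns) {
    v <- features[[nm]]
    if (nm == "chronicity" || is.character(v) || is.factor(v)) {
      v <- as.character(v)
      for (lev in c("subacute", "chronic")) {
        cols[[paste0("chronicity_", lev)]] <- as.numeric(v == lev)
        centers[paste0("chronicity_", lev)] <- 0
        scales[paste0("chronicity_", lev)] <- 1
      }
      next
    }
    v <- as.numeric(v)
    if (startsWith(nm, "Log.") && anyNA(v)) {
      # log column hit non-positive values: recompute with train-min shift
      src <- sub("^Log\\.", "", nm)
      if (!src %in% names(features))
        stop(sprintf("cannot apply shift rule for '%s': '%s' absent",
                     nm, src), call. = FALSE)
      raw <- as.numeric(features[[src]])
      shift <- min(raw) - 1e-6
      v <- log(raw - shift)
      shifts[nm] <- shift
      warning(sprintf("column '%s' uses shifted log (shift %.6g)", nm, shift))
    }
    if (anyNA(v))
      stop(sprintf("column '%s' has missing values", nm), call. = FALSE)
    s <- stats::sd(v)
    if (s == 0)
      stop(sprintf("zero-variance column '%s'", nm), call. = FALSE)
    centers[nm] <- mean(v)
    scales[nm] <- s
    cols[[nm]] <- (v - mean(v)) / s
  }
  Z <- do.call(cbind, cols)
  rownames(Z) <- NULL
  structure(list(Z = Z, S = as.numeric(scores), columns = colnames(Z),
                 centers = centers, scales = scales, log_shifts = shifts,
                 source_columns = columns),
            class = "feature_matrix")
}

#' Normalize new data with a fitted feature matrix's constants
#'
#' @param fm A `feature_matrix` from [assemble_feature_matrix()].
#' @param features New feature data frame (same source columns).
#' @return n x p matrix normalized with the stored (training) constants.
#' @export
apply_feature_normalization <- function(fm, features) {
  stopifnot(inherits(fm, "feature_matrix"))
  cols <- list()
  for (nm in fm$source_columns) {
    v <- features[[nm]]
    if (is.null(v))
      stop(sprintf("missing feature column '%s'", nm), call. = FALSE)
    if (nm == "chronicity" || is.character(v) || is.factor(v)) {
      v <- as.character(v)
      for (lev in c("subacute", "chronic"))
        cols[[paste0("chronicity_", lev)]] <- as.numeric(v == lev)
      next
    }
    v <- as.numeric(v)
    if (startsWith(nm, "Log.") && nm %in% names(fm$log_shifts)) {
      src <- sub("^Log\\.", "", nm)
      raw <- as.numeric(features[[src]])
      v <- log(pmax(raw - fm$log_shifts[nm], 1e-12))
    }
    cols[[nm]] <- (v - fm$centers[nm]) / fm$scales[nm]
  }
  Z <- do.call(cbind, cols)
  Z[, fm$columns, drop = FALSE]
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d sessions x %d covariates\n",
              nrow(x$Z), ncol(x$Z)))
  invisible(x)
}

#' Permutation threshold for variable-score correlations
#'
#' Estimates the magnitude of Pearson correlations expected under the
#' null of no variable-score association, by permuting the scores
#' across samples and recomputing every per-column correlation.
#' Returns both a quantile of the pooled null |r| distribution and the
#' null standard deviation of r (close to `1/sqrt(n-1)` for
#' independent data), which can serve as a reporting threshold.
#'
#' @param Z Numeric covariate matrix (n x p).
#' @param scores Numeric score vector of length n.
#' @param n_perm Number of permutations (>= 100).
#' @param quantile Quantile of the pooled null |r| distribution.
#' @param seed Optional RNG seed for reproducibility.
#' @return List with `threshold` (requested quantile of null |r|),
#'   `null_sd` (SD of null r), `quantile`, `n_perm`.
#' @export
permutation_threshold <- function(Z, scores, n_perm = 1000,
                                  quantile = 0.95, seed = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n < 10L) stop("need at least 10 samples", call. = FALSE)
  if (n_perm < 100L) stop("need at least 100 permutations", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  null_r <- replicate(n_perm, as.vector(stats::cor(Z, sample(scores))))
  null_r <- as.vector(null_r)
  list(threshold = unname(stats::quantile(abs(null_r), quantile)),
       null_sd = stats::sd(null_r), quantile = quantile, n_perm = n_perm)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
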