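#' Planar hand trajectory for one hand in one session
#'
#' A `hand_path` stores the timestamped planar positions of one hand
#' during a rehabilitation session.  Positions are in metres in a
#' session-local frame: `lateral` is the left/right axis (the principal
#' movement axis of horizontal reaching protocols) and `frontal` the
#' front/back axis.  `frontal` may be omitted for tasks that only
#' require lateral displacements.
#'
#' @param times Numeric vector of timestamps in seconds, strictly
#'   increasing, nominally sampled at ~100 Hz (step ~0.01 s).
#' @param lateral Numeric vector of lateral positions (m), same length
#'   as `times`.
#' @param frontal Optional numeric vector of frontal positions (m).
#' @param side Which limb the path belongs to, `"paretic"` or
#'   `"non_paretic"`.
#'
#' @return An object of class `hand_path`.
#' @export
hand_path <- function(times, lateral, frontal = NULL,
                      side = c("paretic", "non_paretic")) {
  side <- match.arg(side)
  times <- as.numeric(times)
  lateral <- as.numeric(lateral)
  if (length(times) < 2L)
    stop("a hand path needs at least 2 samples", call. = FALSE)
  if (length(lateral) != length(times))
    stop("'times' and 'lateral' must have the same length", call. = FALSE)
  if (!all(is.finite(times)) || !all(is.finite(lateral)))
    stop("hand path values must all be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (!is.null(frontal)) {
    frontal <- as.numeric(frontal)
    if (length(frontal) != length(times))
      stop("'frontal' must have the same length as 'times'", call. = FALSE)
    if (!all(is.finite(frontal)))
      stop("hand path values must all be finite", call. = FALSE)
  }
  structure(list(times = times, lateral = lateral, frontal = frontal,
                 side = side),
            class = "hand_path")
}

#' @export
print.hand_path <- function(x, ...) {
  dur <- diff(range(x$times))
  cat(sprintf("<hand_path> %s hand, %d samples over %.1f s (%s)\n",
              x$side, length(x$times), dur,
              if (is.null(x$frontal)) "1 axis" else "2 axes"))
  invisible(x)
}

n_samples <- function(path) length(path$times)

path_axis <- function(path, axis = c("lateral", "frontal")) {
  axis <- match.arg(axis)
  v <- path[[axis]]
  if (is.null(v))
    stop(sprintf("hand path has no '%s' axis", axis), call. = FALSE)
  v
}

#' One training session: paths, task events, metadata, optional scores
#'
#' Bundles both hands' trajectories with the task-event record (target
#' hits/misses), the adaptive-difficulty trace, patient metadata and,
#' when available, clinical scores.  Scores are validated against their
#' scale ranges: FM-UE in \[0, 66\], CAHAI in \[13, 91\], BI in
#' \[0, 100\].
#'
#' @param patient_id Opaque patient token.
#' @param session_index Positive integer, ordinal of the session within
#'   the patient's rehabilitation trajectory.
#' @param paths Named list with elements `paretic` and `non_paretic`,
#'   each a [hand_path].
#' @param events Data frame with columns `time` (s) and `outcome`
#'   (`"hit"`/`"miss"`); may have zero rows.
#' @param difficulty_trace Numeric vector of unitless difficulty values
#'   sampled over the session.
#' @param metadata List with entries `age`, `gender`,
#'   `dominant_side_affected`, `days_post_stroke`, `sessions_completed`.
#' @param scores Optional list with any of `fm_ue`, `cahai`, `bi` and an
#'   `assessment_date` (days, numeric).
#' @param session_date Session date in days (numeric, arbitrary origin).
#'
#' @return An object of class `session_record`.
#' @export
session_record <- function(patient_id, session_index, paths,
                           events = data.frame(time = numeric(),
                                               outcome = character()),
                           difficulty_trace = numeric(),
                           metadata = list(), scores = NULL,
                           session_date = NA_real_) {
  stopifnot(is.list(paths))
  if (!all(c("paretic", "non_paretic") %in% names(paths)))
    stop("'paths' must contain 'paretic' and 'non_paretic' entries",
         call. = FALSE)
  for (p in paths)
    if (!inherits(p, "hand_path"))
      stop("each path must be a 'hand_path'", call. = FALSE)
  session_index <- as.integer(session_index)
  if (is.na(session_index) || session_index < 1L)
    stop("'session_index' must be a positive integer", call. = FALSE)
  if (nrow(events) > 0L) {
    if (!all(c("time", "outcome") %in% names(events)))
      stop("'events' needs columns 'time' and 'outcome'", call. = FALSE)
    if (!all(events$outcome %in% c("hit", "miss")))
      stop("event outcomes must be 'hit' or 'miss'", call. = FALSE)
    span <- range(paths$paretic$times)
    if (any(events$time < span[1] - 1e-9 | events$time > span[2] + 1e-9))
      stop("event times must lie within the session time span",
           call. = FALSE)
  }
  if (length(difficulty_trace) && !all(is.finite(difficulty_trace)))
    stop("'difficulty_trace' must be finite", call. = FALSE)
  if (!is.null(scores)) validate_scores(scores)
  structure(list(patient_id = as.character(patient_id),
                 session_index = session_index,
                 paths = paths, events = events,
                 difficulty_trace = as.numeric(difficulty_trace),
                 metadata = metadata, scores = scores,
                 session_date = as.numeric(session_date)),
            class = "session_record")
}

#' Clinical scale ranges
#'
#' Lower and upper bounds of the three supported clinical scales.
#' @return Named list of `c(lower, upper)` pairs.
#' @export
scale_ranges <- function() {
  list(fm_ue = c(0, 66), cahai = c(13, 91), bi = c(0, 100))
}

validate_scores <- function(scores) {
  rng <- scale_ranges()
  for (nm in intersect(names(rng), names(scores))) {
    v <- scores[[nm]]
    if (is.null(v) || is.na(v)) next
    if (v < rng[[nm]][1] || v > rng[[nm]][2])
      stop(sprintf("score '%s' = %g outside its scale range [%g, %g]",
                   nm, v, rng[[nm]][1], rng[[nm]][2]), call. = FALSE)
  }
  invisible(scores)
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> patient %s, session %d, %d events\n",
              x$patient_id, x$session_index, nrow(x$events)))
  invisible(x)
}

#' Discard the first and last minutes of a session trajectory
#'
#' Kinematic descriptors are computed on the central part of a session
#' only: the beginning and end of a training session are contaminated by
#' instruction revision, postural adjustments and the final score
#' screen.  By default the first and last two minutes are removed.
#'
#' @param path A [hand_path].
#' @param head_s Seconds removed at the start (default 120).
#' @param tail_s Seconds removed at the end (default 120).
#'
#' @return A [hand_path] restricted to times in
#'   `[t0 + head_s, t_end - tail_s)`.
#' @export
trim_session <- function(path, head_s = 120, tail_s = 120) {
  stopifnot(inherits(path, "hand_path"), head_s >= 0, tail_s >= 0)
  t0 <- path$times[1]
  t1 <- path$times[length(path$times)]
  if (t1 - t0 <= head_s + tail_s)
    stop("session too short to trim", call. = FALSE)
  keep <- path$times >= t0 + head_s &
    (if (tail_s > 0) path$times < t1 - tail_s else TRUE)
  if (sum(keep) < 2L)
    stop("session too short to trim", call. = FALSE)
  hand_path(path$times[keep], path$lateral[keep],
            frontal = if (is.null(path$frontal)) NULL else path$frontal[keep],
            side = path$side)
}
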