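#' Dataset-assembly rules
#'
#' Quality rules used when coupling clinical scores to sessions and
#' building the analysis datasets: scores couple to the nearest session
#' within `max_score_coupling_days` (inclusive); the first
#' `exclude_first_sessions` sessions of each patient are dropped
#' (familiarisation); recovery pairs need a gap strictly greater than
#' `recovery_min_gap_days`; retest pairs a gap strictly below
#' `retest_max_gap_hours`.
#'
#' @param max_score_coupling_days Maximum score-session separation in
#'   days (default 4, inclusive).
#' @param exclude_first_sessions Number of initial sessions excluded
#'   per patient (default 2).
#' @param recovery_min_gap_days Minimum recovery-pair gap in days
#'   (default 16, strict).
#' @param retest_max_gap_hours Maximum retest-pair gap in hours
#'   (default 48, strict).
#' @return List of class `assembly_rules`.
#' @export
assembly_rules <- function(max_score_coupling_days = 4,
                           exclude_first_sessions = 2,
                           recovery_min_gap_days = 16,
                           retest_max_gap_hours = 48) {
  stopifnot(max_score_coupling_days > 0, exclude_first_sessions >= 0,
            recovery_min_gap_days > 0, retest_max_gap_hours > 0)
  structure(list(max_score_coupling_days = max_score_coupling_days,
                 exclude_first_sessions = exclude_first_sessions,
                 recovery_min_gap_days = recovery_min_gap_days,
                 retest_max_gap_hours = retest_max_gap_hours),
            class = "assembly_rules")
}

#' Write and read session logs
#'
#' A session is stored as three plain-text files sharing a prefix:
#' `<prefix>_samples.tsv` (columns `time_s`, `hand`, `x_m`, `y_m`),
#' `<prefix>_events.tsv` (`time_s`, `outcome`, `difficulty`) and
#' `<prefix>_meta.json` (identifiers, metadata, scores).  Numeric
#' values are written at full precision so that a write/read round
#' trip reproduces the record exactly.  Malformed files are rejected
#' with the offending line number.
#'
#' @param record A [session_record].
#' @param prefix File-path prefix (directory must exist).
#' @return `read_session_log()` returns the restored [session_record].
#' @export
write_session_log <- function(record, prefix) {
  stopifnot(inherits(record, "session_record"))
  num17 <- function(x) sprintf("%.17g", x) # lossless double round trip
  rows <- lapply(c("paretic", "non_paretic"), function(h) {
    p <- record$paths[[h]]
    data.table::data.table(
      time_s = num17(p$times), hand = h, x_m = num17(p$lateral),
      y_m = if (is.null(p$frontal)) NA_character_ else num17(p$frontal))
  })
  data.table::fwrite(data.table::rbindlist(rows),
                     paste0(prefix, "_samples.tsv"), sep = "\t")
  ev <- record$events
  ntr <- length(record$difficulty_trace)
  diffcol <- if (ntr == nrow(ev)) num17(record$difficulty_trace)
             else rep(NA_character_, nrow(ev))
  data.table::fwrite(data.table::data.table(
    time_s = num17(ev$time), outcome = ev$outcome, difficulty = diffcol),
    paste0(prefix, "_events.tsv"), sep = "\t")
  meta <- list(patient_id = record$patient_id,
               session_index = record$session_index,
               session_date = record$session_date,
               metadata = record$metadata, scores = record$scores,
               two_axis = !is.null(record$paths$paretic$frontal),
               extra_difficulty = if (ntr != nrow(ev))
                 record$difficulty_trace else NULL)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(prefix)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(prefix) {
  sf <- paste0(prefix, "_samples.tsv")
  ef <- paste0(prefix, "_events.tsv")
  mf <- paste0(prefix, "_meta.json")
  for (f in c(sf, ef, mf))
    if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  samples <- data.table::fread(sf, sep = "\t")
  needed <- c("time_s", "hand", "x_m")
  miss <- setdiff(needed, names(samples))
  if (length(miss))
    stop("sample file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_hand <- which(!samples$hand %in% c("paretic", "non_paretic"))
  if (length(bad_hand))
    stop(sprintf("unknown hand token at line %d of %s",
                 bad_hand[1] + 1L, sf), call. = FALSE)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  two_axis <- isTRUE(meta$two_axis) && "y_m" %in% names(samples)
  paths <- list()
  for (h in c("paretic", "non_paretic")) {
    rows <- which(samples$hand == h)
    tm <- samples$time_s[rows]
    dec <- which(diff(tm) <= 0)
    if (length(dec))
      stop(sprintf("non-increasing time at line %d of %s",
                   rows[dec[1] + 1L] + 1L, sf), call. = FALSE)
    paths[[h]] <- hand_path(tm, samples$x_m[rows],
                            frontal = if (two_axis) samples$y_m[rows],
                            side = h)
  }
  events <- data.table::fread(ef, sep = "\t")
  if (!all(c("time_s", "outcome") %in% names(events)))
    stop("event file missing columns", call. = FALSE)
  if (nrow(events)) {
    bad <- which(!events$outcome %in% c("hit", "miss"))
    if (length(bad))
      stop(sprintf("unknown outcome token '%s' at line %d of %s",
                   events$outcome[bad[1]], bad[1] + 1L, ef), call. = FALSE)
  }
  trace <- if (!is.null(meta$extra_difficulty))
    as.numeric(meta$extra_difficulty) else as.numeric(events$difficulty)
  if (anyNA(trace)) trace <- numeric(0)
  scores <- meta$scores
  if (!is.null(scores)) scores <- as.list(scores)
  session_record(meta$patient_id, meta$session_index, paths,
                 events = data.frame(time = as.numeric(events$time_s),
                                     outcome = as.character(events$outcome),
                                     stringsAsFactors = FALSE),
                 difficulty_trace = trace,
                 metadata = as.list(meta$metadata), scores = scores,
                 session_date = meta$session_date %||% NA_real_)
}

#' Assemble the analysis datasets from sessions and clinical scores
#'
#' Applies the assembly rules to a pool of sessions and a clinical
#' score table: builds (1) the cross-sectional set coupling each score
#' to the nearest-in-time eligible session of the same patient within
#' the coupling window, one score to one session; (2) recovery pairs,
#' same-patient cross-sectional samples separated by more than the
#' recovery gap; and (3) retest pairs, same-patient sessions (score
#' not required) separated by less than the retest window.  Exclusion
#' counts are reported.
#'
#' @param sessions List of [session_record]s with `session_date` set.
#' @param score_table Data frame with columns `patient_id`,
#'   `assessment_date` (days) and one column per scale (e.g. `fm_ue`).
#' @param rules An [assembly_rules].
#' @return List with `cross_sectional` (data frame: score row index,
#'   session index, gap), `recovery_pairs`, `retest_pairs`, `counts`.
#' @export
build_analysis_datasets <- function(sessions, score_table,
                                    rules = assembly_rules()) {
  sess_tab <- data.frame(
    idx = seq_along(sessions),
    patient_id = vapply(sessions, function(s) s$patient_id, character(1)),
    session_index = vapply(sessions, function(s) s$session_index,
                           integer(1)),
    date = vapply(sessions, function(s) s$session_date, numeric(1)))
  eligible <- sess_tab$session_index > rules$exclude_first_sessions
  n_first_excluded <- sum(!eligible)
  pool <- sess_tab[eligible, , drop = FALSE]

  cross <- data.frame(score_row = integer(), session = integer(),
                      gap_days = numeric())
  used <- integer(0)
  n_too_far <- 0L
  if (!is.null(score_table) && nrow(score_table)) {
    ord <- order(score_table$assessment_date)
    for (r in ord) {
      cand <- pool[pool$patient_id == score_table$patient_id[r], ,
                   drop = FALSE]
      if (!nrow(cand)) { n_too_far <- n_too_far + 1L; next }
      gap <- abs(cand$date - score_table$assessment_date[r])
      ok <- gap <= rules$max_score_coupling_days & !cand$idx %in% used
      cand <- cand[ok, , drop = FALSE]; gap <- gap[ok]
      if (!nrow(cand)) { n_too_far <- n_too_far + 1L; next }
      best <- order(gap, cand$date)[1L] # ties: earlier session
      cross <- rbind(cross, data.frame(score_row = r,
                                       session = cand$idx[best],
                                       gap_days = gap[best]))
      used <- c(used, cand$idx[best])
    }
  }

  recovery <- data.frame(first = integer(), second = integer(),
                         gap_days = numeric())
  if (nrow(cross) > 1L) {
    pid <- score_table$patient_id[cross$score_row]
    dt <- sess_tab$date[cross$session]
    for (i in seq_len(nrow(cross) - 1L)) for (j in (i + 1L):nrow(cross)) {
      if (pid[i] != pid[j]) next
      gap <- abs(dt[j] - dt[i])
      if (gap > rules$recovery_min_gap_days)
        recovery <- rbind(recovery,
                          data.frame(first = if (dt[i] <= dt[j]) i else j,
                                     second = if (dt[i] <= dt[j]) j else i,
                                     gap_days = gap))
    }
  }

  retest <- data.frame(test = integer(), retest = integer(),
                       gap_hours = numeric())
  taken <- integer(0)
  if (nrow(pool) > 1L) {
    ppool <- pool[order(pool$patient_id, pool$date), , drop = FALSE]
    for (i in seq_len(nrow(ppool) - 1L)) {
      if (ppool$idx[i] %in% taken) next
      j <- i + 1L
      if (ppool$patient_id[j] != ppool$patient_id[i]) next
      if (ppool$idx[j] %in% taken) next
      gap_h <- (ppool$date[j] - ppool$date[i]) * 24
      if (gap_h < rules$retest_max_gap_hours) {
        retest <- rbind(retest, data.frame(test = ppool$idx[i],
                                           retest = ppool$idx[j],
                                           gap_hours = gap_h))
        taken <- c(taken, ppool$idx[i], ppool$idx[j])
      }
    }
  }

  counts <- list(sessions = length(sessions),
                 excluded_familiarisation = n_first_excluded,
                 scores_unmatched = n_too_far,
                 cross_sectional = nrow(cross),
                 recovery_pairs = nrow(recovery),
                 retest_pairs = nrow(retest))
  message(sprintf(paste0("assembled %d cross-sectional samples, %d ",
                         "recovery pairs, %d retest pairs (%d sessions ",
                         "excluded as familiarisation, %d scores ",
                         "unmatched)"),
                  counts$cross_sectional, counts$recovery_pairs,
                  counts$retest_pairs, counts$excluded_familiarisation,
                  counts$scores_unmatched))
  list(cross_sectional = cross, recovery_pairs = recovery,
       retest_pairs = retest, counts = counts)
}
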