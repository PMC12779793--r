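#' Read trial-level session records from CSV
#'
#' Expects an RFC-4180 CSV with header
#' `student_id,skill_id,session_id,trial_index,outcome`, one row per trial,
#' `outcome` binary (1 = correct). Duplicate
#' (student, skill, session, trial_index) keys, non-binary outcomes and
#' non-positive trial indices are rejected with the offending row numbers.
#'
#' @param path path to the CSV file.
#' @return a data frame of validated trial records.
#' @seealso [aggregate_trials()], [generate_trials()]
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) {
    stop("trial file not found: ", path, call. = FALSE)
  }
  rec <- tryCatch(
    utils::read.csv(path, colClasses = "character", strip.white = TRUE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  needed <- c("student_id", "skill_id", "session_id", "trial_index",
              "outcome")
  missing <- setdiff(needed, names(rec))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(rec) == 0L) stop("no records in ", path, call. = FALSE)
  rec <- rec[needed]
  rec$trial_index <- suppressWarnings(as.numeric(rec$trial_index))
  rec$outcome <- suppressWarnings(as.numeric(rec$outcome))
  rec <- validate_trials(rec)
  rec$trial_index <- as.integer(rec$trial_index)
  rec$outcome <- as.integer(rec$outcome)
  rec
}

validate_trials <- function(rec) {
  bad <- which(!rec$outcome %in% c(0L, 1L))
  if (length(bad) > 0L) {
    stop("non-binary outcome on row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(rec$trial_index) | rec$trial_index < 1 |
                 rec$trial_index != round(rec$trial_index))
  if (length(bad) > 0L) {
    stop("invalid trial_index on row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(rec$student_id, rec$skill_id, rec$session_id,
               rec$trial_index, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop("duplicate (student, skill, session, trial_index) on row(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  rec
}

#' Aggregate trial records into counts
#'
#' Collapses validated trial records into `(n, x)` counts — the number of
#' trials and correct responses — either per session or pooled across
#' sessions, mirroring the two criterion-application practices seen in the
#' field (single-session versus multi-session criteria).
#'
#' @param records a data frame from [read_trials()] or
#'   [generate_trials()].
#' @param scope `"pooled"` (sum across sessions per student and skill) or
#'   `"per_session"` (one count per student, skill and session).
#' @param sessions optional character vector restricting to a subset of
#'   session ids before aggregation.
#' @return a data frame with columns `student_id`, `skill_id`
#'   (and `session_id` for per-session scope), `n`, `x`.
#' @examples
#' rec <- generate_trials(0.8, n_sessions = 2, trials_per_session = 5,
#'                        seed = 1)
#' aggregate_trials(rec, scope = "pooled")
#' @export
aggregate_trials <- function(records, scope = c("pooled", "per_session"),
                             sessions = NULL) {
  scope <- match.arg(scope)
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("`records` must be a nonempty data frame of trial records",
         call. = FALSE)
  }
  if (!is.null(sessions)) {
    records <- records[records$session_id %in% sessions, , drop = FALSE]
    if (nrow(records) == 0L) {
      stop("no records remain after filtering to session(s): ",
           paste(sessions, collapse = ", "), call. = FALSE)
    }
  }
  keys <- if (scope == "per_session") {
    c("student_id", "skill_id", "session_id")
  } else {
    c("student_id", "skill_id")
  }
  agg <- stats::aggregate(records["outcome"], by = records[keys],
                          FUN = function(o) c(n = length(o), x = sum(o)))
  out <- cbind(agg[keys], n = agg$outcome[, "n"], x = agg$outcome[, "x"])
  out[do.call(order, out[keys]), , drop = FALSE]
}

#' Generate synthetic trial records for a student with known mastery
#'
#' Emulates assessment of a student whose true mastery level is `true_p`:
#' independent binary outcomes with success probability `true_p`, arranged
#' into sessions. Deterministic given `seed`; the caller's random state is
#' left untouched.
#'
#' @param true_p latent probability of a correct response, in `[0, 1]`.
#' @param n_sessions positive number of sessions.
#' @param trials_per_session positive number of trials per session.
#' @param seed integer seed.
#' @param student_id,skill_id labels for the generated records.
#' @return a data frame of trial records with the [read_trials()] schema.
#' @export
generate_trials <- function(true_p, n_sessions, trials_per_session,
                            seed = NULL, student_id = "S1",
                            skill_id = "K1") {
  if (length(true_p) != 1L || !is.finite(true_p) || true_p < 0 ||
      true_p > 1) {
    stop("`true_p` must lie in [0, 1]", call. = FALSE)
  }
  if (n_sessions < 1 || trials_per_session < 1) {
    stop("`n_sessions` and `trials_per_session` must be >= 1",
         call. = FALSE)
  }
  total <- n_sessions * trials_per_session
  outcomes <- with_local_seed(seed, stats::rbinom(total, 1L, true_p))
  data.frame(
    student_id = student_id, skill_id = skill_id,
    session_id = rep(sprintf("session%d", seq_len(n_sessions)),
                     each = trials_per_session),
    trial_index = rep(seq_len(trials_per_session), times = n_sessions),
    outcome = outcomes
  )
}

#' Write trial records to CSV
#'
#' @param records a data frame of trial records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
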