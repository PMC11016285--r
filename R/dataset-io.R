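#' Validate a per-trial table
#'
#' Checks the canonical trial schema: `stimulus_value` in `[-1, 1]`,
#' `choice` in `{L, R, Nr}`, `outcome` in `{hit, error, no_response}`
#' consistent with the choice (`no_response` iff `Nr`), strictly increasing
#' onset times, optional `reward_port`.
#'
#' @param trials data.frame of trials.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_trials <- function(trials) {
  required <- c("stimulus_value", "choice", "outcome", "stim_onset_s")
  missing <- setdiff(required, names(trials))
  abort_if(length(missing) > 0,
           paste0("trial table missing column(s): ",
                  paste(missing, collapse = ", ")))
  abort_if(any(abs(trials$stimulus_value) > 1),
           "stimulus_value outside [-1, 1]")
  abort_if(!all(trials$choice %in% CHOICE_LEVELS),
           "choice values outside {L, R, Nr}")
  abort_if(!all(trials$outcome %in% OUTCOME_LEVELS),
           "outcome values outside {hit, error, no_response}")
  abort_if(!identical(trials$outcome == "no_response", trials$choice == "Nr"),
           "outcome must be no_response exactly when choice is Nr")
  abort_if(any(trials$stim_onset_s < 0) ||
             is.unsorted(trials$stim_onset_s, strictly = TRUE),
           "stim_onset_s must be nonnegative and strictly increasing")
  invisible(trials)
}

#' Construct a session
#'
#' Bundles one session's trial table with its physiological traces. Traces
#' are two-column data.frames (`time_s`, `value`) with strictly increasing
#' timebases. A warning is issued if a trace does not cover the span from
#' 60 s before the first onset (clamped at 0) to the end of the last
#' stimulus.
#'
#' @param subject_id,session_id identifiers.
#' @param modality `"auditory"` or `"visual"`.
#' @param trials trial table (validated with [validate_trials()]).
#' @param traces named list of trace data.frames (typically `pupil`, `face`,
#'   `locomotion`); may be empty for behavior-only sessions.
#' @param stage optional training-stage label.
#' @return Object of class `statehmm_session`.
#' @export
session <- function(subject_id, session_id, modality, trials,
                    traces = list(), stage = NA) {
  validate_trials(trials)
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    abort_if(!all(c("time_s", "value") %in% names(tr)),
             sprintf("trace '%s' needs time_s and value columns", nm))
    abort_if(is.unsorted(tr$time_s, strictly = TRUE),
             sprintf("trace '%s' timebase is not strictly increasing", nm))
    onset1 <- trials$stim_onset_s[1]
    span_lo <- max(0, onset1 - 60)
    span_hi <- trials$stim_onset_s[nrow(trials)]
    if (tr$time_s[1] > span_lo + 1e-9 ||
        tr$time_s[length(tr$time_s)] < span_hi)
      warning(sprintf("trace '%s' does not cover the session span", nm),
              call. = FALSE)
  }
  structure(list(subject_id = subject_id, session_id = session_id,
                 modality = modality, trials = trials, traces = traces,
                 stage = stage),
            class = "statehmm_session")
}

#' @export
print.statehmm_session <- function(x, ...) {
  cat(sprintf("Session %s (subject %s, %s): %d trials, %d trace(s)\n",
              x$session_id, x$subject_id, x$modality, nrow(x$trials),
              length(x$traces)))
  invisible(x)
}

#' Write sessions to the tabular on-disk dialect
#'
#' One sub-directory per session containing `trials.csv` plus one
#' `<trace>.csv` (`time_s`, `value`) per trace, and a `meta.csv` with
#' identifiers. An optional ground-truth sidecar (`ground_truth.json`) stores
#' generative parameters and state sequences.
#'
#' @param sessions list of `statehmm_session`.
#' @param dir output directory (created if needed).
#' @param truth optional `synthetic_ground_truth` sidecar.
#' @return `dir`, invisibly.
#' @export
write_sessions <- function(sessions, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in sessions) {
    sd <- file.path(dir, s$session_id)
    dir.create(sd, showWarnings = FALSE)
    utils::write.csv(s$trials, file.path(sd, "trials.csv"),
                     row.names = FALSE)
    for (nm in names(s$traces))
      utils::write.csv(s$traces[[nm]], file.path(sd, paste0(nm, ".csv")),
                       row.names = FALSE)
    utils::write.csv(
      data.frame(subject_id = s$subject_id, session_id = s$session_id,
                 modality = s$modality, stage = s$stage),
      file.path(sd, "meta.csv"), row.names = FALSE
    )
  }
  if (!is.null(truth)) {
    sidecar <- list(
      seed = truth$seed,
      states = lapply(truth$states, function(z) z),
      glmhmm = jsonlite::fromJSON(params_to_json(truth$glmhmm)),
      physio = unclass(truth$physio)
    )
    writeLines(jsonlite::toJSON(sidecar, digits = I(17), auto_unbox = TRUE),
               file.path(dir, "ground_truth.json"))
  }
  invisible(dir)
}

#' Read sessions from disk
#'
#' Reads the tabular dialect written by [write_sessions()]: each
#' sub-directory with a `trials.csv` becomes one validated session; every
#' other `*.csv` except `meta.csv` is read as a trace.
#'
#' @param path directory of session sub-directories.
#' @param format only `"tabular"` is supported; the deposited NWB files can
#'   be exported to this dialect with external tooling.
#' @return List of `statehmm_session`.
#' @export
read_sessions <- function(path, format = "tabular") {
  abort_if(!dir.exists(path), sprintf("path '%s' does not exist", path))
  abort_if(!identical(format, "tabular"),
           "only the tabular session format is supported")
  subdirs <- list.dirs(path, recursive = FALSE)
  subdirs <- subdirs[file.exists(file.path(subdirs, "trials.csv"))]
  abort_if(length(subdirs) == 0, "no session directories with trials.csv")
  lapply(subdirs, function(sd) {
    trials <- utils::read.csv(file.path(sd, "trials.csv"),
                              stringsAsFactors = FALSE)
    meta_path <- file.path(sd, "meta.csv")
    meta <- if (file.exists(meta_path))
      utils::read.csv(meta_path, stringsAsFactors = FALSE)
    else
      data.frame(subject_id = basename(sd), session_id = basename(sd),
                 modality = NA, stage = NA)
    trace_files <- setdiff(list.files(sd, pattern = "\\.csv$"),
                           c("trials.csv", "meta.csv"))
    traces <- lapply(trace_files, function(f)
      utils::read.csv(file.path(sd, f), stringsAsFactors = FALSE))
    names(traces) <- sub("\\.csv$", "", trace_files)
    session(meta$subject_id, meta$session_id, meta$modality, trials,
            traces, stage = meta$stage)
  })
}

#' Read a ground-truth sidecar
#' @param path directory containing `ground_truth.json`.
#' @return `synthetic_ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  f <- file.path(path, "ground_truth.json")
  abort_if(!file.exists(f), "no ground_truth.json in path")
  obj <- jsonlite::fromJSON(f, simplifyVector = TRUE)
  cp <- obj$physio
  structure(
    list(states = lapply(seq_len(if (is.list(obj$states)) length(obj$states)
                                 else nrow(obj$states)),
                         function(i) if (is.list(obj$states))
                           as.integer(obj$states[[i]])
                         else as.integer(obj$states[i, ])),
         glmhmm = params_from_json(jsonlite::toJSON(obj$glmhmm,
                                                    digits = NA,
                                                    auto_unbox = TRUE)),
         physio = physio_coupling(cp$pupil_mean, cp$pupil_sd, cp$face_mean,
                                  cp$face_sd, cp$loco_mean, cp$loco_sd,
                                  cp$pupil_move_corr, cp$persistence),
         seed = obj$seed),
    class = "synthetic_ground_truth"
  )
}

#' Apply session-inclusion filters for one subject
#'
#' Keeps sessions with at least `min_rewards` hit trials, balanced so that
#' each reward port delivered at least a `min_port_share` share of rewards,
#' and (when a stage label is present) from training stages 5 or 6. The
#' subject is includable only when at least `min_sessions` sessions survive.
#' Every exclusion is logged with its reason.
#'
#' @param sessions list of `statehmm_session` from one subject.
#' @param min_rewards minimum hit count per session (default 100).
#' @param min_port_share minimum share of rewards at each port (default 0.2).
#' @param min_sessions minimum surviving sessions for subject inclusion
#'   (default 10).
#' @return Object of class `subject_dataset`: `subject_id`, `sessions`
#'   (included), `includable` flag, `exclusions` (session id -> reason).
#' @export
filter_sessions <- function(sessions, min_rewards = 100,
                            min_port_share = 0.2, min_sessions = 10) {
  abort_if(length(sessions) == 0, "no sessions supplied")
  subjects <- unique(vapply(sessions, `[[`, character(1), "subject_id"))
  abort_if(length(subjects) != 1, "sessions must all come from one subject")
  keep <- logical(length(sessions))
  exclusions <- character(0)
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    stage_ok <- is.na(s$stage) || s$stage %in% c(5, 6)
    hits <- s$trials[s$trials$outcome == "hit", , drop = FALSE]
    n_rewards <- nrow(hits)
    port <- hits$reward_port %||% hits$choice
    shares <- if (n_rewards > 0)
      c(L = mean(port == "L"), R = mean(port == "R")) else c(L = 0, R = 0)
    reason <- if (!stage_ok) "stage"
      else if (n_rewards < min_rewards) "min_rewards"
      else if (min(shares) < min_port_share) "port_balance"
      else NA_character_
    if (is.na(reason)) keep[i] <- TRUE
    else exclusions[s$session_id] <- reason
  }
  structure(list(subject_id = subjects,
                 sessions = sessions[keep],
                 includable = sum(keep) >= min_sessions,
                 exclusions = exclusions),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("Subject %s: %d included session(s), %d excluded, %s\n",
              x$subject_id, length(x$sessions), length(x$exclusions),
              if (x$includable) "includable" else "NOT includable"))
  invisible(x)
}
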