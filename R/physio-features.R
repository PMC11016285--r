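sg_window_ms <- function(measure) {
  switch(measure, pupil = 500, face = 200, locomotion = 200,
         stop("unknown measure '", measure, "'", call. = FALSE))
}

# odd Savitzky-Golay window length in samples for a window in ms
sg_window_samples <- function(window_ms, fs) {
  w <- max(5L, round(window_ms * fs / 1000))
  if (w %% 2L == 0L) w <- w + 1L
  as.integer(w)
}

#' Interpolate short gaps in a trace
#'
#' Runs of missing samples shorter than `max_gap_ms` are filled by linear
#' interpolation between the flanking samples; gaps of `max_gap_ms` or
#' longer (strict threshold), and gaps touching either end of the trace,
#' stay missing.
#'
#' @param trace data.frame with `time_s` and `value` (NA marks dropped
#'   samples).
#' @param max_gap_ms gap-duration threshold in milliseconds (default 200).
#' @return The trace with short gaps filled.
#' @export
interpolate_gaps <- function(trace, max_gap_ms = 200) {
  v <- trace$value
  t <- trace$time_s
  dt_ms <- stats::median(diff(t)) * 1000
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    lo <- starts[i]; hi <- ends[i]
    if (lo == 1L || hi == length(v)) next
    gap_ms <- r$lengths[i] * dt_ms
    if (gap_ms < max_gap_ms - 1e-6) {
      v[lo:hi] <- stats::approx(x = t[c(lo - 1L, hi + 1L)],
                                y = v[c(lo - 1L, hi + 1L)],
                                xout = t[lo:hi])$y
    }
  }
  trace$value <- v
  trace
}

#' Condition a physiological trace
#'
#' Applies a second-order Savitzky-Golay filter at the native sampling rate
#' (500 ms window for pupil, 200 ms for face motion energy and locomotion
#' speed), then upsamples to 1 kHz by linear interpolation. Missing runs
#' (e.g. long pupil gaps) are preserved: the filter is applied to each
#' contiguous valid segment, and 1 kHz samples falling inside a masked raw
#' interval stay missing.
#'
#' @param trace data.frame with `time_s` (strictly increasing, ~uniform) and
#'   `value`.
#' @param measure `"pupil"`, `"face"`, or `"locomotion"` (sets the window).
#' @param target_hz output rate (default 1000).
#' @return Object of class `conditioned_trace`: data.frame `time_s`,
#'   `value`, with attributes `measure` and `session_max`.
#' @export
condition_trace <- function(trace, measure = c("pupil", "face", "locomotion"),
                            target_hz = 1000) {
  measure <- match.arg(measure)
  t <- trace$time_s
  v <- trace$value
  abort_if(length(t) < 2L, "trace too short")
  fs <- 1 / stats::median(diff(t))
  w <- sg_window_samples(sg_window_ms(measure), fs)
  abort_if(sum(!is.na(v)) < w,
           sprintf("trace shorter than the %d-sample filter window", w))

  # filter each contiguous valid run; short runs are left unfiltered
  sm <- v
  r <- rle(!is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    idx <- starts[i]:ends[i]
    if (length(idx) >= w)
      sm[idx] <- signal::sgolayfilt(v[idx], p = 2, n = w)
  }

  out_t <- seq(t[1], t[length(t)], by = 1 / target_hz)
  valid <- !is.na(sm)
  out_v <- stats::approx(t[valid], sm[valid], xout = out_t)$y
  # re-mask output samples inside masked raw intervals
  if (any(!valid)) {
    na_runs <- which(!valid)
    for (i in na_runs) {
      lo <- if (i > 1L) t[i - 1L] else -Inf
      hi <- if (i < length(t)) t[i + 1L] else Inf
      out_v[out_t > lo & out_t < hi] <- NA_real_
    }
  }
  # polynomial smoothing can overshoot below zero at sharp movement onsets;
  # speed is physically nonnegative
  if (measure == "locomotion") out_v <- pmax(out_v, 0)
  structure(data.frame(time_s = out_t, value = out_v),
            class = c("conditioned_trace", "data.frame"),
            measure = measure,
            session_max = max(out_v, na.rm = TRUE))
}

#' Normalize a pupil trace to its session maximum
#'
#' Divides the conditioned pupil trace by its within-session maximum so the
#' largest observed diameter maps to 1, making diameters comparable across
#' sessions and subjects.
#'
#' @param trace a `conditioned_trace` (or any `time_s`/`value` data.frame).
#' @return The trace with `value` in `[0, 1]`.
#' @export
normalize_pupil <- function(trace) {
  m <- max(trace$value, na.rm = TRUE)
  abort_if(!is.finite(m) || m <= 0, "trace maximum must be positive")
  trace$value <- trace$value / m
  attr(trace, "session_max") <- m
  trace
}

#' Pre-stimulus sample of a trace
#'
#' For each trial, the value of the (1 kHz) sample at the last time strictly
#' before stimulus onset; trials whose onset precedes the trace start, or
#' whose pre-stimulus sample is masked, get `NA`.
#'
#' @param trace data.frame with `time_s` and `value`.
#' @param onsets numeric vector of stimulus onset times (s).
#' @return Numeric vector, one value per trial.
#' @export
prestim_values <- function(trace, onsets) {
  idx <- findInterval(onsets - 1e-9, trace$time_s)
  out <- rep(NA_real_, length(onsets))
  ok <- idx >= 1L
  out[ok] <- trace$value[idx[ok]]
  out
}

#' Rolling variability over past trials
#'
#' For trial `t`, the sample standard deviation and coefficient of variation
#' of a per-trial series over trials `t-window .. t-1` (within session, no
#' leakage from trial `t` or later). Trials with fewer than `min_obs`
#' available past values are missing; `cv` is missing when the window mean
#' is zero.
#'
#' @param x per-trial values of one session.
#' @param window number of past trials (default 10).
#' @param min_obs minimum non-missing past values (default 3).
#' @return data.frame with columns `sd` and `cv`.
#' @export
rolling_variability <- function(x, window = 10, min_obs = 3) {
  n <- length(x)
  sd_out <- cv_out <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    lo <- max(1L, t - window)
    if (t == 1L) next
    past <- x[lo:(t - 1L)]
    past <- past[!is.na(past)]
    if (length(past) < min_obs) next
    s <- stats::sd(past)
    m <- mean(past)
    sd_out[t] <- s
    cv_out[t] <- if (m != 0) s / m else NA_real_
  }
  data.frame(sd = sd_out, cv = cv_out)
}

#' Combined movement index
#'
#' Z-scores face motion energy and locomotion speed across all supplied
#' trials (typically all included trials of a subject) and sums them into a
#' single continuous movement index that is, by construction, equally
#' correlated with both inputs when their variances match.
#'
#' @param face,locomotion per-trial values (equal length).
#' @return Numeric movement index per trial.
#' @export
movement_index <- function(face, locomotion) {
  abort_if(length(face) != length(locomotion), "inputs must have equal length")
  zf <- stats::sd(face, na.rm = TRUE)
  zl <- stats::sd(locomotion, na.rm = TRUE)
  abort_if(!is.finite(zf) || zf == 0 || !is.finite(zl) || zl == 0,
           "zero-variance input: movement index undefined")
  (face - mean(face, na.rm = TRUE)) / zf +
    (locomotion - mean(locomotion, na.rm = TRUE)) / zl
}

#' Face motion energy from a frame stack
#'
#' Mean absolute frame-to-frame pixel-intensity change within a region of
#' interest, normalized to the session maximum.
#'
#' @param frames 3-d numeric array `height x width x n_frames`.
#' @param roi optional list with integer vectors `rows` and `cols`; default
#'   the full frame.
#' @return Numeric vector of length `n_frames - 1` with values in `[0, 1]`.
#' @export
motion_energy <- function(frames, roi = NULL) {
  abort_if(length(dim(frames)) != 3L, "frames must be a 3-d array")
  rows <- roi$rows %||% seq_len(dim(frames)[1])
  cols <- roi$cols %||% seq_len(dim(frames)[2])
  n <- dim(frames)[3]
  abort_if(n < 2L, "need at least two frames")
  e <- vapply(2:n, function(f)
    mean(abs(frames[rows, cols, f] - frames[rows, cols, f - 1L])),
    numeric(1))
  m <- max(e)
  if (m > 0) e / m else e
}

#' Per-trial features for a set of sessions
#'
#' Runs the full feature pipeline on each session: gap interpolation
#' (pupil), Savitzky-Golay conditioning, session-max pupil normalization,
#' pre-stimulus sampling, and 10-trial rolling variability; then computes
#' the movement index (and its rolling-SD index) with z-scoring across all
#' supplied trials.
#'
#' @param sessions list of `statehmm_session` with `pupil`, `face` and
#'   `locomotion` traces.
#' @param window rolling-variability window in trials (default 10).
#' @return data.frame, one row per trial, with columns `session`, `trial`,
#'   `pupil`, `face`, `locomotion`, `*_sd10`, `*_cv10`, `movement_index`,
#'   `movement_index_sd10`.
#' @export
trial_features <- function(sessions, window = 10) {
  if (inherits(sessions, "statehmm_session")) sessions <- list(sessions)
  per_session <- lapply(seq_along(sessions), function(s) {
    ses <- sessions[[s]]
    abort_if(!all(c("pupil", "face", "locomotion") %in% names(ses$traces)),
             "sessions need pupil, face and locomotion traces")
    onsets <- ses$trials$stim_onset_s
    vals <- list(
      pupil = prestim_values(
        normalize_pupil(condition_trace(
          interpolate_gaps(ses$traces$pupil), "pupil")), onsets),
      face = prestim_values(condition_trace(ses$traces$face, "face"), onsets),
      locomotion = prestim_values(
        condition_trace(ses$traces$locomotion, "locomotion"), onsets)
    )
    out <- data.frame(session = s, trial = seq_along(onsets))
    for (nm in names(vals)) {
      out[[nm]] <- vals[[nm]]
      rv <- rolling_variability(vals[[nm]], window = window)
      out[[paste0(nm, "_sd10")]] <- rv$sd
      out[[paste0(nm, "_cv10")]] <- rv$cv
    }
    out
  })
  feats <- do.call(rbind, per_session)
  feats$movement_index <- movement_index(feats$face, feats$locomotion)
  feats$movement_index_sd10 <-
    movement_index_from_sd(feats$face_sd10, feats$locomotion_sd10)
  feats
}

# movement-index analogue for the rolling-SD features (z-score then sum)
movement_index_from_sd <- function(face_sd, loco_sd) {
  zf <- stats::sd(face_sd, na.rm = TRUE)
  zl <- stats::sd(loco_sd, na.rm = TRUE)
  if (!is.finite(zf) || zf == 0 || !is.finite(zl) || zl == 0)
    return(rep(NA_real_, length(face_sd)))
  (face_sd - mean(face_sd, na.rm = TRUE)) / zf +
    (loco_sd - mean(loco_sd, na.rm = TRUE)) / zl
}
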