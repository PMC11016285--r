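#' Per-state physiological coupling parameters
#'
#' Encodes how the level, variability, and pupil-movement coupling of the
#' three physiological measures depend on the hidden performance state:
#' per-state means and SDs for session-max-normalized pupil diameter (in
#' `[0, 1]`), normalized face motion energy (in `[0, 1]`), and locomotion
#' speed (m/s), a within-trial AR(1) persistence coefficient, and a per-state
#' pupil-movement correlation.
#'
#' @param pupil_mean,pupil_sd length-`K` numeric; means in `[0, 1]`, SDs >= 0.
#' @param face_mean,face_sd length-`K` numeric; means in `[0, 1]`, SDs >= 0.
#' @param loco_mean,loco_sd length-`K` numeric; means >= 0 (m/s), SDs >= 0.
#' @param pupil_move_corr length-`K` correlation in `[-1, 1]` between the
#'   pupil target and the shared movement factor driving face and locomotion.
#' @param persistence AR(1) coefficient in `[0, 1)` for trace evolution
#'   between trial onsets.
#' @return An object of class `physio_coupling`.
#' @export
physio_coupling <- function(pupil_mean, pupil_sd, face_mean, face_sd,
                            loco_mean, loco_sd, pupil_move_corr,
                            persistence = 0.8) {
  K <- length(pupil_mean)
  lens <- c(length(pupil_sd), length(face_mean), length(face_sd),
            length(loco_mean), length(loco_sd), length(pupil_move_corr))
  abort_if(any(lens != K), "all coupling vectors must have length K")
  abort_if(any(c(pupil_sd, face_sd, loco_sd) < 0), "SDs must be >= 0")
  abort_if(any(pupil_mean < 0 | pupil_mean > 1) ||
             any(face_mean < 0 | face_mean > 1),
           "pupil and face means must lie in [0, 1]")
  abort_if(any(loco_mean < 0), "locomotion means must be >= 0")
  abort_if(any(abs(pupil_move_corr) > 1), "correlations must be in [-1, 1]")
  abort_if(persistence < 0 || persistence >= 1, "persistence must be in [0, 1)")
  structure(list(K = K, pupil_mean = pupil_mean, pupil_sd = pupil_sd,
                 face_mean = face_mean, face_sd = face_sd,
                 loco_mean = loco_mean, loco_sd = loco_sd,
                 pupil_move_corr = pupil_move_corr,
                 persistence = persistence),
            class = "physio_coupling")
}

#' Default 3-state ground truth
#'
#' A sticky 3-state model with well-separated psychometric profiles:
#' state 1 optimal (stimulus-guided responses), state 2 disengaged
#' (no response to either side), state 3 left-biased (left licks regardless
#' of stimulus).
#'
#' @param diag_prob self-transition probability of every state.
#' @return A [glmhmm_params] object with `K = 3`.
#' @export
default_glmhmm_truth <- function(diag_prob = 0.98) {
  w <- array(0, dim = c(3L, 3L, 1L))
  b <- matrix(0, 3L, 3L)
  # optimal: strong stimulus weights, responsive
  w[1L, 1L, ] <- -4; w[1L, 2L, ] <- 4
  b[1L, 1:2] <- 1
  # disengaged: Nr dominates at every stimulus
  b[2L, 1:2] <- -3
  # left bias: responds left regardless of stimulus
  w[3L, 1L, ] <- -0.5
  b[3L, 1L] <- 2.5; b[3L, 2L] <- -1
  off <- (1 - diag_prob) / 2
  A <- matrix(off, 3L, 3L)
  diag(A) <- diag_prob
  glmhmm_params(3L, w, b, A, c(0.5, 0.25, 0.25))
}

#' Default state-coupled physiology
#'
#' Emulates the inverted-U structure of arousal during task performance:
#' intermediate pupil diameter and movement with reduced variability and weak
#' pupil-movement coupling in the optimal state; high pupil, larger
#' variability and strong coupling while disengaged; low-intermediate levels
#' in the biased state. State order matches [default_glmhmm_truth()].
#'
#' @param optimal_pupil pupil mean of the optimal state (default 0.55).
#' @return A [physio_coupling] object with `K = 3`.
#' @export
default_physio_coupling <- function(optimal_pupil = 0.55) {
  physio_coupling(
    pupil_mean = c(optimal_pupil, 0.88, 0.30),
    pupil_sd = c(0.04, 0.08, 0.08),
    face_mean = c(0.48, 0.43, 0.44),
    face_sd = c(0.04, 0.09, 0.08),
    loco_mean = c(0.14, 0.14, 0.14),
    loco_sd = c(0.03, 0.07, 0.06),
    pupil_move_corr = c(0.1, 0.8, 0.6),
    persistence = 0.8
  )
}

#' Configuration of a synthetic experiment
#'
#' Defines the task grid, session structure, ground-truth model and
#' physiological coupling of a simulated experiment. Defaults mirror the
#' recorded task: 1.2 s stimuli, inter-trial intervals of 5 +/- 2 s, stimulus
#' values on the six-value grid `{-1, -0.6, -0.2, 0.2, 0.6, 1}` (three
#' difficulties per side), sessions of a few hundred trials.
#'
#' @param n_sessions number of sessions.
#' @param trials_per_session trials per session.
#' @param modality `"visual"` or `"auditory"`.
#' @param stimulus_grid stimulus values in `[-1, 1]` sampled uniformly.
#' @param glmhmm ground-truth [glmhmm_params].
#' @param physio ground-truth [physio_coupling] (`K` must match).
#' @param iti_mean_s,iti_jitter_s inter-trial interval, uniform on
#'   `[mean - jitter, mean + jitter]` seconds.
#' @param stim_duration_s stimulus duration in seconds.
#' @param sample_hz sampling rate of the generated traces (>= 30).
#' @param seed integer seed.
#' @return An object of class `generative_config`.
#' @export
generative_config <- function(n_sessions = 10, trials_per_session = 400,
                              modality = c("visual", "auditory"),
                              stimulus_grid = c(-1, -0.6, -0.2, 0.2, 0.6, 1),
                              glmhmm = default_glmhmm_truth(),
                              physio = default_physio_coupling(),
                              iti_mean_s = 5, iti_jitter_s = 2,
                              stim_duration_s = 1.2, sample_hz = 30,
                              seed = 1) {
  modality <- match.arg(modality)
  abort_if(n_sessions < 1 || trials_per_session < 1,
           "n_sessions and trials_per_session must be >= 1")
  abort_if(length(stimulus_grid) == 0 || any(abs(stimulus_grid) > 1),
           "stimulus_grid must be nonempty with values in [-1, 1]")
  abort_if(!inherits(glmhmm, "glmhmm_params"), "glmhmm must be glmhmm_params")
  abort_if(!inherits(physio, "physio_coupling"),
           "physio must be physio_coupling")
  abort_if(glmhmm$K != physio$K,
           "glmhmm and physio coupling disagree on the number of states")
  abort_if(iti_mean_s <= 0 || iti_jitter_s < 0 || stim_duration_s <= 0,
           "timing parameters must be positive (jitter nonnegative)")
  abort_if(iti_jitter_s >= iti_mean_s, "iti jitter must be below the mean")
  abort_if(sample_hz < 30, "trace sampling rate must be >= 30 Hz")
  structure(list(n_sessions = as.integer(n_sessions),
                 trials_per_session = as.integer(trials_per_session),
                 modality = modality, stimulus_grid = stimulus_grid,
                 glmhmm = glmhmm, physio = physio,
                 iti_mean_s = iti_mean_s, iti_jitter_s = iti_jitter_s,
                 stim_duration_s = stim_duration_s, sample_hz = sample_hz,
                 seed = as.integer(seed)),
            class = "generative_config")
}

#' Map a stimulus descriptor to its signed task value
#'
#' Auditory tone clouds are valued by the proportion of tones in the
#' right-target octave minus the proportion in the left-target octave.
#' Visual Gabor patches are valued by the normalized angular distance from
#' the 45 degree diagonal, `|angle - 45| / 45`, signed by the side assigned
#' to the nearer cardinal orientation.
#'
#' @param modality `"auditory"` or `"visual"`.
#' @param p_right,p_left auditory: tone proportions in the right/left target
#'   octaves, each in `[0, 1]` with sum <= 1.
#' @param angle visual: Gabor angle in degrees, in `[0, 90]`.
#' @param horizontal_side visual: which response side (`"L"` or `"R"`) the
#'   horizontal-ish category (angle < 45) is assigned to.
#' @return Stimulus value in `[-1, 1]`.
#' @examples
#' stimulus_value("auditory", p_right = 1, p_left = 0)     # +1
#' stimulus_value("visual", angle = 18, horizontal_side = "L")  # -0.6
#' @export
stimulus_value <- function(modality = c("auditory", "visual"),
                           p_right = NULL, p_left = NULL,
                           angle = NULL, horizontal_side = c("L", "R")) {
  modality <- match.arg(modality)
  if (modality == "auditory") {
    abort_if(is.null(p_right) || is.null(p_left),
             "auditory stimuli need p_right and p_left")
    abort_if(any(c(p_right, p_left) < 0) || any(c(p_right, p_left) > 1) ||
               p_right + p_left > 1 + 1e-12,
             "octave proportions must be in [0, 1] with sum <= 1")
    return(p_right - p_left)
  }
  horizontal_side <- match.arg(horizontal_side)
  abort_if(is.null(angle), "visual stimuli need an angle")
  abort_if(angle < 0 || angle > 90, "angle must be in [0, 90] degrees")
  magnitude <- abs(angle - 45) / 45
  if (angle == 45) return(0)
  horiz <- angle < 45
  sign <- if ((horiz && horizontal_side == "R") ||
              (!horiz && horizontal_side == "L")) 1 else -1
  sign * magnitude
}

#' Simulate trials and hidden state sequences
#'
#' Draws, per session, a hidden state chain from the ground-truth initial
#' distribution and transition matrix (chains never cross session
#' boundaries), uniform stimuli from the task grid, choices from the true
#' state's multinomial emission, and onset times accumulating stimulus
#' duration plus a uniform inter-trial interval. Outcomes follow the task
#' rule: a lick to the side of the stimulus is a hit, the opposite lick an
#' error, no lick a no-response.
#'
#' @param cfg a [generative_config].
#' @return A list with `sessions` (list of per-session trial tables) and
#'   `truth` (class `synthetic_ground_truth`: generative parameters, coupling
#'   and per-session state sequences).
#' @export
simulate_trials <- function(cfg) {
  abort_if(!inherits(cfg, "generative_config"), "cfg must be generative_config")
  p <- cfg$glmhmm
  abort_if(any(abs(rowSums(p$transition) - 1) > 1e-10),
           "ground-truth transition matrix is not row-stochastic")
  abort_if(p$K != cfg$physio$K, "params and coupling disagree on K")
  set.seed(derive_seed(cfg$seed, 0L))
  sessions <- vector("list", cfg$n_sessions)
  states <- vector("list", cfg$n_sessions)
  for (s in seq_len(cfg$n_sessions)) {
    n <- cfg$trials_per_session
    z <- integer(n)
    z[1L] <- sample.int(p$K, 1L, prob = p$init_prob)
    if (n > 1L) for (t in 2:n)
      z[t] <- sample.int(p$K, 1L, prob = p$transition[z[t - 1L], ])
    u <- sample(cfg$stimulus_grid, n, replace = TRUE)
    choice <- character(n)
    for (t in seq_len(n))
      choice[t] <- sample(CHOICE_LEVELS, 1L, prob = emission_probs(p, z[t], u[t]))
    reward_port <- ifelse(u < 0, "L", ifelse(u > 0, "R",
                                             sample(c("L", "R"), n, TRUE)))
    outcome <- ifelse(choice == "Nr", "no_response",
                      ifelse(choice == reward_port, "hit", "error"))
    iti <- stats::runif(n, cfg$iti_mean_s - cfg$iti_jitter_s,
                        cfg$iti_mean_s + cfg$iti_jitter_s)
    onset <- cumsum(iti + cfg$stim_duration_s) - cfg$stim_duration_s
    sessions[[s]] <- data.frame(
      stimulus_value = u, choice = choice, outcome = outcome,
      stim_onset_s = onset, reward_port = reward_port,
      stringsAsFactors = FALSE
    )
    states[[s]] <- z
  }
  truth <- structure(list(states = states, glmhmm = p, physio = cfg$physio,
                          seed = cfg$seed),
                     class = "synthetic_ground_truth")
  list(sessions = sessions, truth = truth)
}

#' Simulate state-coupled physiological traces
#'
#' For each trial a latent target triple (pupil, face, locomotion) is drawn
#' around the true state's means: a shared standard-normal movement factor
#' drives face and locomotion, and the pupil deviate correlates with that
#' factor by the state's `pupil_move_corr`. Traces evolve between trial
#' onsets by AR(1) relaxation toward the upcoming target, and the sample
#' immediately before each stimulus onset is pinned to the drawn target so
#' pre-stimulus values carry the configured state-conditional moments. Pupil
#' and face are clipped to `[0, 1]` and locomotion to `[0, Inf)`; targets
#' beyond those bounds are truncated, so moments of states whose mean sits
#' close to a bound are matched only approximately.
#'
#' @param truth `synthetic_ground_truth` from [simulate_trials()].
#' @param cfg the same [generative_config].
#' @param sessions the trial tables returned by [simulate_trials()] (needed
#'   for onset times).
#' @return A list (one element per session) of trace lists `pupil`, `face`,
#'   `locomotion`, each a data.frame with `time_s` and `value`.
#' @export
simulate_physio <- function(truth, cfg, sessions) {
  abort_if(!inherits(truth, "synthetic_ground_truth"),
           "truth must come from simulate_trials")
  cp <- cfg$physio
  abort_if(cp$K != truth$glmhmm$K, "coupling K mismatch")
  set.seed(derive_seed(cfg$seed, 1L))
  fs <- cfg$sample_hz
  dt <- 1 / fs
  out <- vector("list", length(sessions))
  for (s in seq_along(sessions)) {
    tr <- sessions[[s]]
    z <- truth$states[[s]]
    n <- nrow(tr)
    # latent per-trial targets with state-dependent moments and coupling
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    r <- cp$pupil_move_corr[z]
    move <- r * z1 + sqrt(1 - r^2) * z2
    pupil_t <- cp$pupil_mean[z] + cp$pupil_sd[z] * z1
    face_t <- cp$face_mean[z] + cp$face_sd[z] * move
    loco_t <- cp$loco_mean[z] + cp$loco_sd[z] * move
    t_end <- tr$stim_onset_s[n] + cfg$stim_duration_s
    times <- seq(0, t_end, by = dt)
    # pre-stimulus anchor = last sample strictly before each onset
    anchor <- findInterval(tr$stim_onset_s - 1e-9, times)
    stim_n <- max(1L, round(cfg$stim_duration_s * fs))
    build <- function(targets, lo, hi) {
      v <- numeric(length(times))
      phi <- cp$persistence
      prev_i <- 1L
      prev_v <- targets[1L]
      v[1L] <- targets[1L]
      for (i in seq_len(n)) {
        a <- anchor[i]
        if (a > prev_i) {
          idx <- (prev_i + 1L):a
          steps <- seq_along(idx)
          # geometric relaxation from the previous value toward the target
          v[idx] <- targets[i] + (prev_v - targets[i]) * phi^steps
        }
        # the target holds through the stimulus window, so the pre-stimulus
        # neighborhood (and hence the smoothed pre-stimulus sample) carries
        # the trial's drawn target
        hold_end <- min(a + stim_n, length(times))
        v[a:hold_end] <- targets[i]
        prev_i <- hold_end
        prev_v <- targets[i]
      }
      if (prev_i < length(times)) v[(prev_i + 1L):length(times)] <- targets[n]
      pmin(pmax(v, lo), hi)
    }
    out[[s]] <- list(
      pupil = data.frame(time_s = times, value = build(pupil_t, 0, 1)),
      face = data.frame(time_s = times, value = build(face_t, 0, 1)),
      locomotion = data.frame(time_s = times,
                              value = build(loco_t, 0, Inf))
    )
  }
  out
}

#' Simulate a complete experiment
#'
#' Convenience wrapper running [simulate_trials()] and [simulate_physio()]
#' and assembling full session objects.
#'
#' @param cfg a [generative_config].
#' @param subject_id subject identifier for the generated sessions.
#' @return List with `sessions` (list of `statehmm_session`) and `truth`.
#' @export
simulate_experiment <- function(cfg, subject_id = "synthetic") {
  sim <- simulate_trials(cfg)
  traces <- simulate_physio(sim$truth, cfg, sim$sessions)
  sessions <- vector("list", length(sim$sessions))
  for (s in seq_along(sim$sessions)) {
    sessions[[s]] <- session(
      subject_id = subject_id,
      session_id = sprintf("%s_%03d", subject_id, s),
      modality = cfg$modality,
      trials = sim$sessions[[s]],
      traces = traces[[s]]
    )
  }
  list(sessions = sessions, truth = sim$truth)
}
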