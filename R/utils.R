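# Internal helpers shared across modules.

CHOICE_LEVELS <- c("L", "R", "Nr")
OUTCOME_LEVELS <- c("hit", "error", "no_response")
STEREOTYPES <- c("optimal", "disengaged", "bias_left", "bias_right",
                 "avoid_left", "avoid_right")

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
}

# choice labels -> integer codes 1 (L), 2 (R), 3 (Nr)
choice_codes <- function(choice) {
  codes <- match(as.character(choice), CHOICE_LEVELS)
  abort_if(anyNA(codes), "choice column contains values outside {L, R, Nr}")
  codes
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# sessions argument normalization: accept a single trial table, a list of
# trial tables, or a list of session objects
as_trial_list <- function(sessions) {
  if (is.data.frame(sessions)) return(list(sessions))
  abort_if(!is.list(sessions) || length(sessions) == 0L,
           "sessions must be a trial table or a nonempty list of them")
  lapply(sessions, function(s) {
    if (inherits(s, "statehmm_session")) s$trials else s
  })
}

# deterministic child seeds derived from one user seed (kept below 2^31)
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483647L
}
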