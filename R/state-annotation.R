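#' Discretize state posteriors into labels
#'
#' A trial is assigned to its maximum-posterior state when that posterior
#' reaches the confidence threshold (inclusive); otherwise the trial is
#' indeterminate (`NA`).
#'
#' @param posterior a `state_posterior` from [forward_backward()], or a
#'   `T x K` gamma matrix.
#' @param threshold minimum posterior probability, in `(0.5, 1]`
#'   (default 0.8).
#' @return Integer vector of state ids (`1..K`) with `NA` for indeterminate
#'   trials.
#' @export
discretize <- function(posterior, threshold = 0.8) {
  gamma <- if (inherits(posterior, "state_posterior")) posterior$gamma
           else as.matrix(posterior)
  abort_if(threshold <= 0.5 || threshold > 1, "threshold must be in (0.5, 1]")
  top <- max.col(gamma, ties.method = "first")
  top_p <- gamma[cbind(seq_len(nrow(gamma)), top)]
  ifelse(top_p >= threshold, top, NA_integer_)
}

# idealized response profiles at u = -1 (left target) and u = +1 (right
# target); rows L, R, Nr
stereotype_profiles <- function() {
  prof <- list(
    optimal     = cbind(left = c(1, 0, 0), right = c(0, 1, 0)),
    disengaged  = cbind(left = c(0, 0, 1), right = c(0, 0, 1)),
    bias_left   = cbind(left = c(1, 0, 0), right = c(1, 0, 0)),
    bias_right  = cbind(left = c(0, 1, 0), right = c(0, 1, 0)),
    avoid_left  = cbind(left = c(0, 0, 1), right = c(0, 1, 0)),
    avoid_right = cbind(left = c(1, 0, 0), right = c(0, 0, 1))
  )
  lapply(prof, function(m) { rownames(m) <- CHOICE_LEVELS; m })
}

#' Classify states into the six stereotypes
#'
#' Evaluates each state's psychometric profile at the easiest stimuli
#' (`u = -1`, left target, and `u = +1`, right target) and assigns one of
#' the six stereotypic categories: `optimal` (correct lick probable on both
#' sides), `disengaged` (no response probable on both sides), `bias_left` /
#' `bias_right` (one lick direction probable regardless of stimulus), and
#' `avoid_right` / `avoid_left` (correct lick to one side, no response to
#' the other). States matching no rule at the 0.5 probability level fall
#' back to the nearest idealized profile by total-variation distance.
#'
#' @param params a [glmhmm_params].
#' @param stimulus_grid grid used to check both stimulus signs are present.
#' @return Object of class `stereotype_map`: `stereotype` (character per
#'   state) and `profile` (per-state response probabilities at `u = -1, +1`).
#' @export
classify_stereotypes <- function(params,
                                 stimulus_grid = c(-1, -0.6, -0.2,
                                                   0.2, 0.6, 1)) {
  abort_if(!any(stimulus_grid < 0) || !any(stimulus_grid > 0),
           "stimulus grid must contain both left (<0) and right (>0) values")
  profiles <- stereotype_profiles()
  stereotype <- character(params$K)
  profile <- vector("list", params$K)
  for (k in seq_len(params$K)) {
    pl <- emission_probs(params, k, -1)  # left-target stimulus
    pr <- emission_probs(params, k, +1)  # right-target stimulus
    profile[[k]] <- cbind(left = pl, right = pr)
    stereotype[k] <-
      if (pl["Nr"] >= 0.5 && pr["Nr"] >= 0.5) "disengaged"
      else if (pl["L"] >= 0.5 && pr["R"] >= 0.5) "optimal"
      else if (pl["L"] >= 0.5 && pr["L"] >= 0.5) "bias_left"
      else if (pl["R"] >= 0.5 && pr["R"] >= 0.5) "bias_right"
      else if (pl["L"] >= 0.5 && pr["Nr"] >= 0.5) "avoid_right"
      else if (pl["Nr"] >= 0.5 && pr["R"] >= 0.5) "avoid_left"
      else {
        tv <- vapply(profiles, function(m)
          0.5 * sum(abs(m[, "left"] - pl)) + 0.5 * sum(abs(m[, "right"] - pr)),
          numeric(1))
        names(tv)[which.min(tv)]
      }
  }
  structure(list(stereotype = stereotype, profile = profile),
            class = "stereotype_map")
}

#' @export
print.stereotype_map <- function(x, ...) {
  cat("State stereotypes:",
      paste(sprintf("%d=%s", seq_along(x$stereotype), x$stereotype),
            collapse = ", "), "\n")
  invisible(x)
}

# per-session epochs: runs of equal labels (indeterminate runs included,
# labeled NA)
label_epochs <- function(labels) {
  n <- length(labels)
  if (n == 0L) return(data.frame(state = integer(0), start = integer(0),
                                 length = integer(0)))
  key <- ifelse(is.na(labels), 0L, labels)
  r <- rle(key)
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  data.frame(state = ifelse(r$values == 0L, NA_integer_, r$values),
             start = start, length = r$lengths)
}

#' Occupancy, dwell-time and transition statistics
#'
#' Computes, across sessions: the fraction of trials spent in each
#' stereotype and in the indeterminate condition, dwell-time distributions
#' (epoch lengths in trials, never merged across session boundaries), and
#' transition durations — lengths of indeterminate runs flanked by two
#' discrete states within a session. Indeterminate runs at session edges
#' count toward indeterminate occupancy but not as transitions.
#'
#' @param labels_per_session list of per-session label vectors from
#'   [discretize()].
#' @param stereotypes a `stereotype_map` (or character vector per state).
#' @return Object of class `dwell_stats`: `occupancy` (named fractions
#'   including `indeterminate`, summing to 1), `dwell` (list of epoch-length
#'   vectors per stereotype), `transition_durations`,
#'   `median_transition`, `indeterminate_fraction`.
#' @export
dwell_stats <- function(labels_per_session, stereotypes) {
  if (is.list(labels_per_session) &&
      !is.null(labels_per_session$gamma))
    labels_per_session <- list(labels_per_session)
  if (!is.list(labels_per_session))
    labels_per_session <- list(labels_per_session)
  abort_if(length(labels_per_session) == 0 ||
             any(vapply(labels_per_session, length, integer(1)) == 0),
           "labels must be nonempty")
  st <- if (inherits(stereotypes, "stereotype_map")) stereotypes$stereotype
        else as.character(stereotypes)

  total <- sum(vapply(labels_per_session, length, integer(1)))
  occ_counts <- stats::setNames(numeric(length(STEREOTYPES)), STEREOTYPES)
  dwell <- stats::setNames(vector("list", length(STEREOTYPES)), STEREOTYPES)
  trans <- integer(0)
  n_ind <- 0L

  for (labels in labels_per_session) {
    n_ind <- n_ind + sum(is.na(labels))
    for (k in seq_along(st))
      occ_counts[st[k]] <- occ_counts[st[k]] + sum(labels == k, na.rm = TRUE)
    ep <- label_epochs(labels)
    for (i in seq_len(nrow(ep))) {
      if (!is.na(ep$state[i])) {
        s <- st[ep$state[i]]
        dwell[[s]] <- c(dwell[[s]], ep$length[i])
      } else if (i > 1L && i < nrow(ep)) {
        trans <- c(trans, ep$length[i])  # flanked by two discrete states
      }
    }
  }
  occupancy <- c(occ_counts / total, indeterminate = n_ind / total)
  structure(list(occupancy = occupancy, dwell = dwell,
                 transition_durations = trans,
                 median_transition = if (length(trans)) stats::median(trans)
                                     else NA_real_,
                 indeterminate_fraction = n_ind / total),
            class = "dwell_stats")
}

#' @export
print.dwell_stats <- function(x, ...) {
  cat("State occupancy:\n")
  occ <- x$occupancy[x$occupancy > 0]
  for (nm in names(occ)) cat(sprintf("  %-13s %.1f%%\n", nm, 100 * occ[nm]))
  if (!is.na(x$median_transition))
    cat(sprintf("Median transition duration: %g trial(s)\n",
                x$median_transition))
  invisible(x)
}
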