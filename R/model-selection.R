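#' Select the number of states by cross-validation
#'
#' Sessions are shuffled with a fixed seed, split round-robin into folds,
#' and for every candidate `K` the best-of-`restarts` EM fit on the training
#' sessions is scored by held-out log-likelihood (or log-posterior
#' normalized without the prior term), normalized per test trial. The chosen
#' `K` is the smallest whose mean test log-likelihood sits within
#' `plateau_tol` nats/trial of the maximum over the scanned range — the
#' operational reading of "maximum of the plateau". A final model with the
#' chosen `K` is then fit by MLE to all sessions (best of restarts).
#'
#' @param sessions list of trial tables / sessions (>= `folds` of them).
#' @param K_max largest state count scanned (default 7).
#' @param folds number of cross-validation folds (default 5).
#' @param restarts EM restarts per fit (default 10).
#' @param prior [prior_config] used for the CV fits (default MAP).
#' @param seed integer seed (fold shuffling + EM restarts).
#' @param plateau_tol plateau tolerance in nats/trial (default 0.002).
#' @param max_iter,tol EM controls for the CV fits.
#' @return Object of class `selection_result`: `test_ll` (mean per-trial
#'   test log-likelihood per K), `fold_ll` (fold x K matrix), `chosen_K`,
#'   `final_fit` (MLE [em_fit] with the chosen K).
#' @export
select_num_states <- function(sessions, K_max = 7, folds = 5, restarts = 10,
                              prior = prior_config("MAP"), seed = 1,
                              plateau_tol = 0.002, max_iter = 150,
                              tol = 1e-3) {
  trials <- as_trial_list(sessions)
  n <- length(trials)
  abort_if(n < folds, "need at least as many sessions as folds")
  set.seed(derive_seed(seed, 0L))
  ord <- sample.int(n)
  fold_of <- integer(n)
  fold_of[ord] <- rep_len(seq_len(folds), n)

  fold_ll <- matrix(NA_real_, folds, K_max)
  for (f in seq_len(folds)) {
    train <- trials[fold_of != f]
    test <- trials[fold_of == f]
    n_test <- sum(vapply(test, nrow, integer(1)))
    for (K in seq_len(K_max)) {
      fit <- em_fit(train, K, prior = prior,
                    seed = derive_seed(seed, f * 100L + K),
                    restarts = if (K == 1L) 1L else restarts,
                    max_iter = max_iter, tol = tol)
      ll <- sum(vapply(test, function(tr)
        forward_backward(fit$params, tr)$loglik, numeric(1)))
      fold_ll[f, K] <- ll / n_test
    }
  }
  test_ll <- colMeans(fold_ll)
  chosen_K <- min(which(test_ll >= max(test_ll) - plateau_tol))

  final_fit <- em_fit(trials, chosen_K, prior = prior_config("MLE"),
                      seed = derive_seed(seed, 9999L),
                      restarts = if (chosen_K == 1L) 1L else restarts,
                      max_iter = max_iter, tol = tol)
  structure(list(test_ll = test_ll, fold_ll = fold_ll, chosen_K = chosen_K,
                 K_max = K_max, plateau_tol = plateau_tol,
                 final_fit = final_fit),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Cross-validated state-count selection\n")
  cat("  mean test log-likelihood per trial by K:\n")
  cat("  ", paste(sprintf("K=%d: %.4f", seq_along(x$test_ll), x$test_ll),
                  collapse = "  "), "\n")
  cat("  chosen K:", x$chosen_K, "\n")
  invisible(x)
}

# contiguous block of test trials for fold f out of `folds`
block_indices <- function(n, f, folds) {
  edges <- round(seq(0, n, length.out = folds + 1))
  (edges[f] + 1L):edges[f + 1L]
}

#' Cross-validated choice prediction
#'
#' Within each session, contiguous blocks of `1/folds` of the trials are
#' withheld in rotation. A model is trained on the remaining trials of every
#' session (the segments flanking each withheld block enter as independent
#' chains). For each test trial the state belief is filtered forward over
#' the trials preceding the block, propagated through the transition matrix
#' across every intervening withheld trial, and the trial's choice is
#' predicted as the argmax category of the argmax state's GLM at the trial's
#' stimulus. Ties in either argmax break toward the lowest index.
#'
#' @param sessions list of trial tables / sessions.
#' @param K number of states.
#' @param folds number of rotating block folds (default 5, i.e. 20% blocks).
#' @param prior [prior_config] for the fold models.
#' @param restarts EM restarts per fold model.
#' @param seed integer seed.
#' @param max_iter,tol EM controls.
#' @return Object of class `prediction_result`: `accuracy`, `n_trials`,
#'   `predicted` / `observed` per-trial vectors (concatenated over
#'   sessions, in session order).
#' @export
predict_choices <- function(sessions, K, folds = 5, prior = prior_config("MAP"),
                            restarts = 3, seed = 1, max_iter = 150,
                            tol = 1e-3) {
  trials <- as_trial_list(sessions)
  abort_if(K < 1, "K must be >= 1")
  for (tr in trials)
    abort_if(nrow(tr) < folds, "withheld block longer than session")

  predicted <- lapply(trials, function(tr) character(nrow(tr)))
  for (f in seq_len(folds)) {
    # training chains: contiguous segments around each withheld block
    train_segments <- list()
    for (s in seq_along(trials)) {
      n <- nrow(trials[[s]])
      blk <- block_indices(n, f, folds)
      pre <- seq_len(min(blk) - 1L)
      post <- if (max(blk) < n) (max(blk) + 1L):n else integer(0)
      if (length(pre) > 0)
        train_segments[[length(train_segments) + 1L]] <- trials[[s]][pre, ]
      if (length(post) > 0)
        train_segments[[length(train_segments) + 1L]] <- trials[[s]][post, ]
    }
    fit <- em_fit(train_segments, K, prior = prior,
                  seed = derive_seed(seed, f), restarts = restarts,
                  max_iter = max_iter, tol = tol)
    p <- fit$params
    for (s in seq_along(trials)) {
      tr <- trials[[s]]
      n <- nrow(tr)
      blk <- block_indices(n, f, folds)
      pre <- seq_len(min(blk) - 1L)
      belief <- if (length(pre) > 0) {
        filter_forward(p, tr[pre, , drop = FALSE])
      } else p$init_prob
      for (t in blk) {
        gap <- t - (if (length(pre) > 0) max(pre) else 0L)
        b <- belief
        for (g in seq_len(gap - (if (length(pre) > 0) 0L else 1L)))
          b <- as.numeric(b %*% p$transition)
        state <- which.max(b)
        probs <- emission_probs(p, state, tr$stimulus_value[t])
        predicted[[s]][t] <- CHOICE_LEVELS[which.max(probs)]
      }
    }
  }
  pred <- unlist(predicted)
  obs <- unlist(lapply(trials, function(tr) as.character(tr$choice)))
  structure(list(accuracy = mean(pred == obs), n_trials = length(obs),
                 predicted = pred, observed = obs, K = K),
            class = "prediction_result")
}

# filtered state distribution after the last trial of `trials`
filter_forward <- function(params, trials) {
  d <- session_design(trials)
  logB <- emission_loglik_matrix(params, d$U, d$y)
  la <- log(params$init_prob) + logB[1, ]
  logA <- log(params$transition)
  n <- nrow(logB)
  if (n > 1L) for (t in 2:n) {
    la <- vapply(seq_len(params$K), function(j)
      logsumexp(la + logA[, j]), numeric(1)) + logB[t, ]
  }
  p <- exp(la - logsumexp(la))
  p / sum(p)
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "Cross-validated choice prediction: K = %d, accuracy = %.1f%% (%d trials)\n",
    x$K, 100 * x$accuracy, x$n_trials))
  invisible(x)
}
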