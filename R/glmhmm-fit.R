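#' Prior configuration for GLM-HMM fitting
#'
#' MAP fitting places a zero-mean Gaussian prior (variance
#' `gaussian_variance`) on every free GLM weight and bias, and a symmetric
#' Dirichlet prior (concentration `dirichlet_alpha`) on each row of the
#' transition matrix. MLE fitting uses no prior.
#'
#' @param mode `"MAP"` or `"MLE"`.
#' @param gaussian_variance positive prior variance for weights/biases.
#' @param dirichlet_alpha positive Dirichlet concentration for transitions.
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(mode = c("MAP", "MLE"), gaussian_variance = 2,
                         dirichlet_alpha = 2) {
  mode <- match.arg(mode)
  abort_if(gaussian_variance <= 0 || dirichlet_alpha <= 0,
           "prior hyperparameters must be positive")
  structure(list(mode = mode, gaussian_variance = gaussian_variance,
                 dirichlet_alpha = dirichlet_alpha),
            class = "prior_config")
}

# log prior density of params under a prior_config (0 for MLE)
prior_logdensity <- function(params, prior) {
  if (prior$mode == "MLE") return(0)
  free_w <- c(params$weights[, 1:2, ], params$biases[, 1:2])
  gauss <- sum(stats::dnorm(free_w, 0, sqrt(prior$gaussian_variance),
                            log = TRUE))
  a <- prior$dirichlet_alpha
  K <- params$K
  dir_row <- function(row) {
    lgamma(K * a) - K * lgamma(a) + sum((a - 1) * log(pmax(row, 1e-300)))
  }
  gauss + sum(apply(params$transition, 1L, dir_row))
}

#' Exact state inference for one session
#'
#' Forward-backward smoothing in log space: per-trial posterior state
#' probabilities given the whole session, summed pairwise transition
#' posteriors (for the EM M-step), and the session log marginal likelihood.
#'
#' @param params a [glmhmm_params] object.
#' @param trials trial table with `stimulus_value` and `choice` columns.
#' @return An object of class `state_posterior` with elements `gamma`
#'   (`T x K`), `xi` (`K x K` expected transition counts), `loglik`.
#' @export
forward_backward <- function(params, trials) {
  d <- session_design(trials)
  logB <- emission_loglik_matrix(params, d$U, d$y)
  abort_if(anyNA(logB), "NaN in emission log-likelihoods")
  res <- fb_cpp(logB, log(params$transition), log(params$init_prob))
  structure(list(gamma = res$gamma, xi = res$xi, loglik = res$loglik,
                 n_trials = nrow(d$U)),
            class = "state_posterior")
}

#' Log-likelihood or log-posterior of parameters
#'
#' Sum of per-session log marginal likelihoods; under a MAP prior the log
#' prior density of the parameters is added.
#'
#' @param params a [glmhmm_params] object.
#' @param sessions a trial table or list of trial tables / sessions.
#' @param prior a [prior_config].
#' @return Scalar log-likelihood (MLE) or log-posterior (MAP).
#' @export
log_posterior <- function(params, sessions, prior = prior_config("MLE")) {
  trials <- as_trial_list(sessions)
  ll <- sum(vapply(trials, function(tr) forward_backward(params, tr)$loglik,
                   numeric(1)))
  ll + prior_logdensity(params, prior)
}

# pack/unpack free emission parameters of one state for the optimizer:
# (D weights + bias) for L, then for R; Nr fixed at zero
pack_state_par <- function(params, k) {
  D <- params$D
  c(params$weights[k, 1L, ], params$biases[k, 1L],
    params$weights[k, 2L, ], params$biases[k, 2L])
}

unpack_state_par <- function(params, k, par) {
  D <- params$D
  params$weights[k, 1L, ] <- par[seq_len(D)]
  params$biases[k, 1L] <- par[D + 1L]
  params$weights[k, 2L, ] <- par[D + 1L + seq_len(D)]
  params$biases[k, 2L] <- par[2L * (D + 1L)]
  params
}

random_init <- function(K, D) {
  w <- array(0, dim = c(K, 3L, D))
  b <- matrix(0, K, 3L)
  w[, 1:2, ] <- stats::rnorm(K * 2L * D)
  b[, 1:2] <- stats::rnorm(K * 2L)
  A <- matrix(stats::runif(K * K, 0, 0.1), K, K) + diag(K) * 0.9
  A <- A / rowSums(A)
  glmhmm_params(K, w, b, A, rep(1 / K, K))
}

#' Fit a multinomial GLM-HMM by expectation-maximization
#'
#' Each session is an independent chain: forward-backward restarts at the
#' initial distribution for every session and transitions never span session
#' boundaries. The M-step sets the transition matrix from expected transition
#' counts (plus Dirichlet pseudo-counts under MAP), the initial distribution
#' from expected initial-state counts, and maximizes the posterior-weighted
#' multinomial log-likelihood of each state's GLM numerically (BFGS with
#' analytic gradients, warm-started), with a Gaussian penalty under MAP. The
#' objective (log-likelihood or log-posterior) is non-decreasing across
#' iterations.
#'
#' @param sessions a trial table or list of trial tables / sessions.
#' @param K number of hidden states.
#' @param prior a [prior_config]; default MAP with variance 2, alpha 2.
#' @param seed integer seed controlling random initialization.
#' @param max_iter maximum EM iterations.
#' @param tol stop when the objective improves by less than `tol`.
#' @param restarts number of random initializations; the fit with the best
#'   final objective is returned.
#' @param init optional [glmhmm_params] to start from (overrides restarts).
#' @param init_prob_mode `"estimate"` re-estimates the initial distribution
#'   each M-step; `"uniform"` keeps it fixed at `1/K`.
#' @return An object of class `glmhmm_fit`: `params`, `objective` (final),
#'   `trace` (objective per iteration), `converged`, `n_iter`, `prior`.
#' @examples
#' \donttest{
#' cfg <- generative_config(n_sessions = 3, trials_per_session = 150, seed = 1)
#' sim <- simulate_trials(cfg)
#' fit <- em_fit(sim$sessions, K = 3, seed = 1, restarts = 2)
#' fit$params
#' }
#' @export
em_fit <- function(sessions, K, prior = prior_config("MAP"), seed = 1,
                   max_iter = 300, tol = 1e-4, restarts = 1, init = NULL,
                   init_prob_mode = c("estimate", "uniform")) {
  init_prob_mode <- match.arg(init_prob_mode)
  trials <- as_trial_list(sessions)
  designs <- lapply(trials, session_design)
  K <- as.integer(K)
  abort_if(K < 1L, "K must be >= 1")

  if (!is.null(init)) restarts <- 1L
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, r))
    start <- init %||% random_init(K, ncol(designs[[1]]$U))
    fit <- em_once(designs, start, prior, max_iter, tol, init_prob_mode)
    if (is.null(best) || fit$objective > best$objective) best <- fit
  }
  best$prior <- prior
  best
}

em_once <- function(designs, params, prior, max_iter, tol, init_prob_mode) {
  K <- params$K
  lambda <- if (prior$mode == "MAP") 1 / prior$gaussian_variance else 0
  pseudo <- if (prior$mode == "MAP") prior$dirichlet_alpha - 1 else 0
  trace <- numeric(0)
  obj_prev <- -Inf
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    # E-step
    ll <- 0
    xi_sum <- matrix(0, K, K)
    gamma1 <- matrix(0, length(designs), K)
    gammas <- vector("list", length(designs))
    for (s in seq_along(designs)) {
      d <- designs[[s]]
      logB <- emission_loglik_matrix(params, d$U, d$y)
      res <- fb_cpp(logB, log(params$transition), log(params$init_prob))
      ll <- ll + res$loglik
      xi_sum <- xi_sum + res$xi
      gamma1[s, ] <- res$gamma[1, ]
      gammas[[s]] <- res$gamma
    }
    obj <- ll + prior_logdensity(params, prior)
    trace <- c(trace, obj)
    if (obj - obj_prev < tol && iter > 1L) {
      converged <- TRUE
      break
    }
    abort_if(obj < obj_prev - 1e-8,
             sprintf("EM objective decreased at iteration %d (%.6g -> %.6g)",
                     iter, obj_prev, obj))
    obj_prev <- obj

    # M-step: transitions and initial distribution
    if (K > 1L) {
      A <- xi_sum + pseudo
      rs <- rowSums(A)
      zero <- rs <= 0
      A[zero, ] <- 1 / K
      A[!zero, ] <- A[!zero, , drop = FALSE] / rs[!zero]
      params$transition <- A
      if (init_prob_mode == "estimate") {
        p0 <- colSums(gamma1)
        params$init_prob <- p0 / sum(p0)
      }
    }

    # M-step: per-state GLM weights
    U_all <- do.call(rbind, lapply(designs, `[[`, "U"))
    y_all <- unlist(lapply(designs, `[[`, "y"))
    g_all <- do.call(rbind, gammas)
    for (k in seq_len(K)) {
      par0 <- pack_state_par(params, k)
      g_k <- g_all[, k]
      # memoize the joint value/gradient evaluation: BFGS queries fn and gr
      # at the same point back to back
      last_par <- NULL
      last_res <- NULL
      eval_obj <- function(p) {
        if (is.null(last_par) || !identical(p, last_par)) {
          last_res <<- mnl_obj_cpp(p, U_all, y_all, g_k, 3L, lambda)
          last_par <<- p
        }
        last_res
      }
      opt <- stats::optim(
        par0,
        fn = function(p) eval_obj(p)$value,
        gr = function(p) eval_obj(p)$grad,
        method = "BFGS", control = list(maxit = 100, reltol = 1e-12)
      )
      f0 <- mnl_nll_cpp(par0, U_all, y_all, g_k, 3L, lambda)
      if (opt$value <= f0) params <- unpack_state_par(params, k, opt$par)
    }
  }

  # final Newton polish of each state's GLM at the last posteriors: BFGS
  # stalls once the objective is flat to ~1e-10, which leaves parameters
  # ~1e-6 from the optimum; a couple of Newton steps (finite-difference
  # Hessian over the analytic gradient) close that gap. This is one more
  # generalized M-step, so the objective cannot decrease.
  U_all <- do.call(rbind, lapply(designs, `[[`, "U"))
  y_all <- unlist(lapply(designs, `[[`, "y"))
  g_all <- do.call(rbind, lapply(designs, function(d) {
    logB <- emission_loglik_matrix(params, d$U, d$y)
    fb_cpp(logB, log(params$transition), log(params$init_prob))$gamma
  }))
  for (k in seq_len(K))
    params <- unpack_state_par(params, k,
                               newton_polish(pack_state_par(params, k),
                                             U_all, y_all, g_all[, k],
                                             lambda))

  structure(list(params = params, objective = trace[length(trace)],
                 trace = trace, converged = converged,
                 n_iter = length(trace)),
            class = "glmhmm_fit")
}

newton_polish <- function(par, U, y, g, lambda, steps = 3) {
  np <- length(par)
  f0 <- mnl_nll_cpp(par, U, y, g, 3L, lambda)
  for (s in seq_len(steps)) {
    gr <- mnl_grad_cpp(par, U, y, g, 3L, lambda)
    if (max(abs(gr)) < 1e-10) break
    h <- 1e-6
    H <- matrix(0, np, np)
    for (j in seq_len(np)) {
      e <- numeric(np); e[j] <- h
      H[, j] <- (mnl_grad_cpp(par + e, U, y, g, 3L, lambda) -
                   mnl_grad_cpp(par - e, U, y, g, 3L, lambda)) / (2 * h)
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H + diag(1e-10, np), gr),
                     error = function(e) NULL)
    if (is.null(step)) break
    cand <- par - step
    f1 <- mnl_nll_cpp(cand, U, y, g, 3L, lambda)
    if (!is.finite(f1) || f1 > f0) break
    par <- cand
    f0 <- f1
  }
  par
}

#' @export
print.glmhmm_fit <- function(x, ...) {
  cat(sprintf("GLM-HMM fit: K = %d, objective = %.3f, %d EM iterations%s\n",
              x$params$K, x$objective, x$n_iter,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Align estimated states to a reference parameter set
#'
#' The GLM-HMM likelihood is invariant to permuting state labels; recovery
#' analyses therefore align fitted states to the generative ones by the
#' permutation minimizing total squared weight/bias distance.
#'
#' @param est,ref [glmhmm_params] with equal `K`.
#' @return Integer permutation `p` such that estimated state `p[k]`
#'   corresponds to reference state `k`.
#' @export
align_states <- function(est, ref) {
  abort_if(est$K != ref$K, "state counts differ")
  K <- est$K
  perms <- permutations_of(K)
  cost <- function(p) {
    sum((est$weights[p, , , drop = FALSE] - ref$weights)^2) +
      sum((est$biases[p, , drop = FALSE] - ref$biases)^2)
  }
  perms[[which.min(vapply(perms, cost, numeric(1)))]]
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permutations_of(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Apply a state permutation to parameters
#' @param params a [glmhmm_params].
#' @param perm integer permutation as returned by [align_states()].
#' @return Re-labeled [glmhmm_params] (state `k` of the result is state
#'   `perm[k]` of the input).
#' @export
permute_states <- function(params, perm) {
  glmhmm_params(params$K,
                params$weights[perm, , , drop = FALSE],
                params$biases[perm, , drop = FALSE],
                params$transition[perm, perm, drop = FALSE],
                params$init_prob[perm])
}
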