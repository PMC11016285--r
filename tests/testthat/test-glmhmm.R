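test_that("emission probabilities are a correct softmax over L, R, Nr", {
  p0 <- glmhmm_params(1, matrix(0, 1, 3), matrix(0, 1, 3),
                      matrix(1), 1)
  expect_equal(unname(emission_probs(p0, 1, 0.4)), rep(1 / 3, 3))

  # shift invariance: adding a constant to every logit leaves probs unchanged
  p1 <- glmhmm_params(1, matrix(c(-3, 3, 0), 1), matrix(0, 1, 3),
                      matrix(1), 1)
  base <- emission_probs(p1, 1, 1)
  expect_equal(sum(base), 1)
  # hand-computed softmax of logits (-3, 3, 0), to four decimals
  expect_true(max(abs(base - c(0.0024, 0.9503, 0.0473))) < 5e-5)
  expect_equal(unname(base),
               exp(c(-3, 3, 0)) / sum(exp(c(-3, 3, 0))), tolerance = 1e-12)
})

test_that("parameter validation rejects malformed inputs", {
  expect_error(glmhmm_params(2, array(0, c(2, 3, 1)), matrix(0, 2, 3),
                             matrix(c(0.5, 0.5, 0.2, 0.7), 2, 2),
                             c(0.5, 0.5)),
               "sum to 1")
  b <- matrix(0, 1, 3); b[1, 3] <- 1
  expect_error(glmhmm_params(1, matrix(0, 1, 3), b, matrix(1), 1),
               "reference")
})

test_that("forward-backward matches brute-force path enumeration", {
  cases <- expand.grid(K = 1:3, T_n = c(2, 5, 8))
  for (i in seq_len(nrow(cases))) {
    K <- cases$K[i]; T_n <- cases$T_n[i]
    params <- random_params(K, seed = 100 + i)
    trials <- random_session(params, T_n, seed = 200 + i)
    fb <- forward_backward(params, trials)
    expect_equal(fb$loglik, enumerate_loglik(params, trials),
                 tolerance = 1e-10)
    expect_true(all(abs(rowSums(fb$gamma) - 1) < 1e-10))
  }
})

test_that("single-state and absorbing-chain posteriors are degenerate", {
  params <- random_params(1, seed = 1)
  trials <- random_session(params, 20, seed = 2)
  fb <- forward_backward(params, trials)
  expect_true(all(fb$gamma == 1))
  by_hand <- sum(vapply(seq_len(20), function(t)
    log(emission_probs(params, 1, trials$stimulus_value[t])[
      match(trials$choice[t], c("L", "R", "Nr"))]), numeric(1)))
  expect_equal(fb$loglik, by_hand, tolerance = 1e-12)

  p2 <- random_params(2, seed = 3)
  p2$transition <- diag(2)
  p2$init_prob <- c(1, 0)
  fb2 <- forward_backward(p2, trials)
  expect_true(all(fb2$gamma[, 1] == 1))
})

test_that("EM objective is non-decreasing under MLE and MAP", {
  truth <- default_glmhmm_truth()
  sessions <- lapply(1:3, function(s) random_session(truth, 120, seed = s))
  for (seed in 1:5) {
    for (mode in c("MLE", "MAP")) {
      fit <- em_fit(sessions, K = 2, prior = prior_config(mode),
                    seed = seed, max_iter = 40, tol = 1e-6)
      expect_true(all(diff(fit$trace) >= -1e-8),
                  label = sprintf("monotone trace (seed %d, %s)", seed, mode))
    }
  }
})

test_that("K=1 MLE fit equals the pooled multinomial logistic MLE", {
  truth <- glmhmm_params(1, matrix(c(-2, 2.5, 0), 1),
                         matrix(c(0.5, 0.8, 0), 1), matrix(1), 1)
  trials <- random_session(truth, 600, seed = 11)
  fit <- em_fit(trials, K = 1, prior = prior_config("MLE"), seed = 1,
                max_iter = 20, tol = 1e-10)
  # independent convex-optimization oracle from a cold start
  u <- trials$stimulus_value
  y <- match(trials$choice, c("L", "R", "Nr"))
  opt <- oracle_mnl_fit(u, y)
  est <- c(fit$params$weights[1, 1, ], fit$params$biases[1, 1],
           fit$params$weights[1, 2, ], fit$params$biases[1, 2])
  expect_equal(unname(est), opt$par, tolerance = 1e-6)
})

test_that("reference-category gauge does not change fitted probabilities", {
  truth <- glmhmm_params(1, matrix(c(-2, 2, 0), 1),
                         matrix(c(0.3, -0.2, 0), 1), matrix(1), 1)
  trials <- random_session(truth, 500, seed = 21)
  fit <- em_fit(trials, K = 1, prior = prior_config("MLE"), seed = 1,
                max_iter = 20, tol = 1e-10)
  # unconstrained softmax oracle: free parameters for all three categories
  u <- trials$stimulus_value
  y <- match(trials$choice, c("L", "R", "Nr"))
  nll_free <- function(par) {
    -sum(vapply(seq_along(u), function(t) {
      logits <- par[c(1, 3, 5)] * u[t] + par[c(2, 4, 6)]
      logits[y[t]] - log(sum(exp(logits)))
    }, numeric(1)))
  }
  opt <- optim(rep(0.1, 6), nll_free, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  for (uu in c(-1, -0.5, 0, 0.5, 1)) {
    logits <- opt$par[c(1, 3, 5)] * uu + opt$par[c(2, 4, 6)]
    p_free <- exp(logits) / sum(exp(logits))
    expect_equal(unname(emission_probs(fit$params, 1, uu)), p_free,
                 tolerance = 1e-4)
  }
})

test_that("log-posterior decomposes as log-likelihood plus prior density", {
  params <- random_params(2, seed = 5)
  sessions <- lapply(1:2, function(s) random_session(params, 50, seed = s))
  prior <- prior_config("MAP")
  mle <- log_posterior(params, sessions, prior_config("MLE"))
  map <- log_posterior(params, sessions, prior)
  expect_equal(mle, sum(vapply(sessions, function(tr)
    forward_backward(params, tr)$loglik, numeric(1))), tolerance = 1e-12)

  # closed-form prior at zero weights and uniform transitions
  K <- 2
  zero <- glmhmm_params(K, array(0, c(K, 3, 1)), matrix(0, K, 3),
                        matrix(0.5, K, K), c(0.5, 0.5))
  gauss <- 2 * K * 2 * dnorm(0, 0, sqrt(2), log = TRUE)
  dir <- K * (lgamma(2 * K) - K * lgamma(2) + (2 - 1) * K * log(1 / K))
  expect_equal(log_posterior(zero, sessions, prior) -
                 log_posterior(zero, sessions, prior_config("MLE")),
               gauss + dir, tolerance = 1e-10)
  expect_equal(map - mle, statehmm:::prior_logdensity(params, prior),
               tolerance = 1e-10)
})

test_that("likelihood is invariant under state relabeling", {
  params <- random_params(3, seed = 7)
  trials <- random_session(params, 60, seed = 8)
  perm <- c(3L, 1L, 2L)
  permuted <- permute_states(params, perm)
  expect_equal(forward_backward(params, trials)$loglik,
               forward_backward(permuted, trials)$loglik, tolerance = 1e-10)
  expect_equal(align_states(permuted, params), order(perm))
})

test_that("parameters round-trip exactly through JSON", {
  params <- random_params(3, seed = 9)
  back <- params_from_json(params_to_json(params))
  expect_identical(back$weights, params$weights)
  expect_identical(back$transition, params$transition)
  expect_identical(back$init_prob, params$init_prob)
})
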