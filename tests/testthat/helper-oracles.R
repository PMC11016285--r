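# Independent oracles and fixture builders used across tests.

# brute-force log marginal likelihood by enumerating all K^T state paths
enumerate_loglik <- function(params, trials) {
  u <- trials$stimulus_value
  y <- match(trials$choice, c("L", "R", "Nr"))
  T_n <- length(u)
  K <- params$K
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_n)))
  lik <- 0
  for (r in seq_len(nrow(paths))) {
    z <- paths[r, ]
    p <- params$init_prob[z[1]] * emission_probs(params, z[1], u[1])[y[1]]
    if (T_n > 1) for (t in 2:T_n) {
      p <- p * params$transition[z[t - 1], z[t]] *
        emission_probs(params, z[t], u[t])[y[t]]
    }
    lik <- lik + p
  }
  log(as.numeric(lik))
}

# random valid parameter set for property tests
random_params <- function(K, seed) {
  set.seed(seed)
  w <- array(0, dim = c(K, 3, 1))
  b <- matrix(0, K, 3)
  w[, 1:2, ] <- rnorm(2 * K)
  b[, 1:2] <- rnorm(2 * K)
  A <- matrix(rexp(K * K), K, K)
  A <- A / rowSums(A)
  pi0 <- rexp(K)
  glmhmm_params(K, w, b, A, pi0 / sum(pi0))
}

# random short session drawn from a parameter set
random_session <- function(params, T_n, seed) {
  set.seed(seed)
  u <- sample(c(-1, -0.6, -0.2, 0.2, 0.6, 1), T_n, replace = TRUE)
  z <- integer(T_n)
  z[1] <- sample.int(params$K, 1, prob = params$init_prob)
  if (T_n > 1) for (t in 2:T_n)
    z[t] <- sample.int(params$K, 1, prob = params$transition[z[t - 1], ])
  choice <- vapply(seq_len(T_n), function(t)
    sample(c("L", "R", "Nr"), 1, prob = emission_probs(params, z[t], u[t])),
    character(1))
  data.frame(stimulus_value = u, choice = choice,
             outcome = ifelse(choice == "Nr", "no_response",
                              ifelse((u < 0) == (choice == "L"),
                                     "hit", "error")),
             stim_onset_s = seq_len(T_n) * 6.2,
             stringsAsFactors = FALSE)
}

# pooled multinomial logistic negative log-likelihood and gradient
# (Nr reference), independent of the package's C++ objective
oracle_mnl_nll <- function(par, u, y_codes) {
  wl <- par[1]; bl <- par[2]; wr <- par[3]; br <- par[4]
  ll <- 0
  for (t in seq_along(u)) {
    logits <- c(wl * u[t] + bl, wr * u[t] + br, 0)
    ll <- ll + logits[y_codes[t]] - log(sum(exp(logits)))
  }
  -ll
}

oracle_mnl_grad <- function(par, u, y_codes) {
  wl <- par[1]; bl <- par[2]; wr <- par[3]; br <- par[4]
  g <- numeric(4)
  for (t in seq_along(u)) {
    logits <- c(wl * u[t] + bl, wr * u[t] + br, 0)
    p <- exp(logits - max(logits))
    p <- p / sum(p)
    rl <- p[1] - (y_codes[t] == 1)
    rr <- p[2] - (y_codes[t] == 2)
    g <- g + c(rl * u[t], rl, rr * u[t], rr)
  }
  g
}

oracle_mnl_fit <- function(u, y_codes) {
  optim(rep(0, 4), oracle_mnl_nll, gr = oracle_mnl_grad, u = u,
        y_codes = y_codes, method = "BFGS",
        control = list(maxit = 2000, reltol = 1e-16))
}

# trial table with a specified hit pattern, for filter tests
make_filter_session <- function(id, hits_L, hits_R, errors = 10,
                                subject = "m1", stage = NA) {
  n <- hits_L + hits_R + errors
  choice <- c(rep("L", hits_L), rep("R", hits_R), rep("Nr", errors))
  outcome <- c(rep("hit", hits_L + hits_R), rep("no_response", errors))
  port <- c(rep("L", hits_L), rep("R", hits_R), rep("L", errors))
  trials <- data.frame(
    stimulus_value = rep(c(-1, 1), length.out = n),
    choice = choice, outcome = outcome,
    stim_onset_s = seq_len(n) * 6.2, reward_port = port,
    stringsAsFactors = FALSE
  )
  session(subject, id, "visual", trials, stage = stage)
}

# small complete synthetic experiment shared by feature/analysis tests
shared_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generative_config(n_sessions = 4, trials_per_session = 250,
                               seed = 42)
      cache <<- simulate_experiment(cfg)
    }
    cache
  }
})
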