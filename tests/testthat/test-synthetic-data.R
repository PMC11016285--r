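test_that("stimulus values follow the task definitions", {
  expect_equal(stimulus_value("auditory", p_right = 1, p_left = 0), 1)
  expect_equal(stimulus_value("auditory", p_right = 0, p_left = 1), -1)
  expect_equal(stimulus_value("auditory", p_right = 0.3, p_left = 0.3), 0)
  expect_equal(stimulus_value("visual", angle = 45), 0)
  expect_equal(stimulus_value("visual", angle = 18, horizontal_side = "L"),
               -0.6)
  expect_equal(stimulus_value("visual", angle = 72, horizontal_side = "L"),
               0.6)
  expect_equal(stimulus_value("visual", angle = 0, horizontal_side = "R"), 1)
  expect_error(stimulus_value("visual", angle = 95), "angle")
  expect_error(stimulus_value("auditory", p_right = 0.8, p_left = 0.5),
               "proportions")
})

test_that("degenerate emissions and transitions behave as configured", {
  # forced-left single state
  forced <- glmhmm_params(1, matrix(0, 1, 3),
                          matrix(c(50, -50, 0), 1), matrix(1), 1)
  cfg <- generative_config(n_sessions = 2, trials_per_session = 50,
                           glmhmm = forced,
                           physio = physio_coupling(0.5, 0, 0.5, 0, 0.1, 0,
                                                    0, 0),
                           seed = 3)
  sim <- simulate_trials(cfg)
  expect_true(all(unlist(lapply(sim$sessions, `[[`, "choice")) == "L"))

  # identity transitions: sessions never leave their initial state
  truth2 <- glmhmm_params(2, array(0, c(2, 3, 1)),
                          matrix(c(2, 2, -2, -2, 0, 0), 2), diag(2),
                          c(0.5, 0.5))
  cfg2 <- generative_config(n_sessions = 6, trials_per_session = 40,
                            glmhmm = truth2,
                            physio = physio_coupling(c(0.4, 0.6), c(0, 0),
                                                     c(0.5, 0.5), c(0, 0),
                                                     c(0.1, 0.1), c(0, 0),
                                                     c(0, 0), 0),
                            seed = 4)
  sim2 <- simulate_trials(cfg2)
  for (z in sim2$truth$states) expect_equal(length(unique(z)), 1L)
})

test_that("seeded generation is bit-reproducible", {
  cfg <- generative_config(n_sessions = 2, trials_per_session = 60, seed = 9)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$truth$states, b$truth$states)
  expect_identical(a$sessions[[1]]$trials, b$sessions[[1]]$trials)
  expect_identical(a$sessions[[2]]$traces$pupil, b$sessions[[2]]$traces$pupil)
})

test_that("simulated choices match the emission model within binomial error", {
  cfg <- generative_config(n_sessions = 10, trials_per_session = 400,
                           seed = 7)
  sim <- simulate_trials(cfg)
  truth <- cfg$glmhmm
  z <- unlist(sim$truth$states)
  trials <- do.call(rbind, sim$sessions)
  for (k in 1:3) {
    for (u in c(-1, 0.6)) {
      idx <- z == k & trials$stimulus_value == u
      n <- sum(idx)
      expect_gt(n, 30)
      p_true <- emission_probs(truth, k, u)
      for (cc in c("L", "R", "Nr")) {
        phat <- mean(trials$choice[idx] == cc)
        se <- sqrt(max(p_true[cc] * (1 - p_true[cc]), 1e-4) / n)
        expect_lt(abs(phat - p_true[cc]), 4 * se + 0.01)
      }
    }
  }
})

test_that("state-chain transition frequencies match the generative matrix", {
  cfg <- generative_config(n_sessions = 30, trials_per_session = 400,
                           seed = 11)
  sim <- simulate_trials(cfg)
  A <- cfg$glmhmm$transition
  counts <- matrix(0, 3, 3)
  for (z in sim$truth$states)
    for (t in 2:length(z)) counts[z[t - 1], z[t]] <- counts[z[t - 1], z[t]] + 1
  expect_gte(sum(counts), 10000)
  for (k in 1:3) {
    gof <- suppressWarnings(chisq.test(counts[k, ], p = A[k, ]))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("pre-stimulus physiology carries the configured state moments", {
  # noiseless limit: SD 0, persistence 0 -> samples equal the state means
  coup0 <- physio_coupling(c(0.3, 0.6, 0.9), c(0, 0, 0),
                           c(0.5, 0.5, 0.5), c(0, 0, 0),
                           c(0.1, 0.1, 0.1), c(0, 0, 0),
                           c(0, 0, 0), 0)
  cfg0 <- generative_config(n_sessions = 1, trials_per_session = 80,
                            physio = coup0, seed = 5)
  exp0 <- simulate_experiment(cfg0)
  ses <- exp0$sessions[[1]]
  z <- exp0$truth$states[[1]]
  pre <- prestim_values(ses$traces$pupil, ses$trials$stim_onset_s)
  expect_equal(pre, c(0.3, 0.6, 0.9)[z], tolerance = 1e-12)

  # Monte-Carlo check of the optimal-state mean
  coup <- physio_coupling(c(0.6, 0.9, 0.3), c(0.05, 0.05, 0.05),
                          c(0.5, 0.5, 0.5), c(0.05, 0.05, 0.05),
                          c(0.1, 0.1, 0.1), c(0.02, 0.02, 0.02),
                          c(0, 0, 0), 0.8)
  cfg <- generative_config(n_sessions = 6, trials_per_session = 300,
                           physio = coup, seed = 6)
  sim <- simulate_experiment(cfg)
  pre <- unlist(lapply(sim$sessions, function(s)
    prestim_values(s$traces$pupil, s$trials$stim_onset_s)))
  z <- unlist(sim$truth$states)
  n1 <- sum(z == 1)
  expect_lt(abs(mean(pre[z == 1]) - 0.6), 3 * 0.05 / sqrt(n1))
})

test_that("per-state pupil-movement correlations are recovered", {
  coup <- physio_coupling(c(0.55, 0.85, 0.35), c(0.05, 0.08, 0.08),
                          c(0.48, 0.43, 0.44), c(0.05, 0.08, 0.07),
                          c(0.14, 0.14, 0.14), c(0.03, 0.06, 0.05),
                          pupil_move_corr = c(0.1, 0.8, 0.6),
                          persistence = 0.5)
  cfg <- generative_config(n_sessions = 25, trials_per_session = 400,
                           physio = coup, seed = 13)
  sim <- simulate_trials(cfg)
  traces <- simulate_physio(sim$truth, cfg, sim$sessions)
  z <- unlist(sim$truth$states)
  pupil <- unlist(lapply(seq_along(traces), function(s)
    prestim_values(traces[[s]]$pupil, sim$sessions[[s]]$stim_onset_s)))
  face <- unlist(lapply(seq_along(traces), function(s)
    prestim_values(traces[[s]]$face, sim$sessions[[s]]$stim_onset_s)))
  for (k in 1:3) {
    expect_gt(sum(z == k), 1500)
    r_hat <- cor(pupil[z == k], face[z == k])
    expect_lt(abs(r_hat - coup$pupil_move_corr[k]), 0.1)
  }
})

test_that("generator rejects inconsistent configurations", {
  expect_error(physio_coupling(0.5, -0.1, 0.5, 0, 0.1, 0, 0, 0), "SDs")
  expect_error(generative_config(glmhmm = default_glmhmm_truth(),
                                 physio = physio_coupling(0.5, 0, 0.5, 0,
                                                          0.1, 0, 0, 0)),
               "number of states")
  cfg <- generative_config(n_sessions = 1, trials_per_session = 10, seed = 1)
  cfg$glmhmm$transition[1, ] <- c(0.5, 0.4, 0.2)
  expect_error(simulate_trials(cfg), "row-stochastic")
})
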