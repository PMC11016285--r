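# build a binned_state_prob object directly from bin-level data
make_binned <- function(centers, p_opt, counts) {
  bins <- data.frame(center = centers, count = counts,
                     usable = counts >= 20)
  for (st in c("optimal", "disengaged", "bias_left", "bias_right",
               "avoid_left", "avoid_right", "indeterminate"))
    bins[[st]] <- 0
  bins$optimal <- p_opt
  bins$disengaged <- 1 - p_opt
  structure(list(bins = bins, measure = "pupil", min_count = 20),
            class = "binned_state_prob",
            data_range = range(centers))
}

test_that("binned state probabilities are row-normalized proportions", {
  set.seed(7)
  n <- 4000
  feats <- data.frame(pupil = runif(n))
  all_opt <- binned_state_prob(feats, rep("optimal", n))
  probs <- all_opt$bins$optimal
  expect_true(all(probs[all_opt$bins$count > 0] == 1))
  cats <- c("optimal", "disengaged", "bias_left", "bias_right",
            "avoid_left", "avoid_right", "indeterminate")
  expect_true(all(abs(rowSums(all_opt$bins[, cats]) - 1) < 1e-10))

  # labels independent of the measure: bin proportions near global occupancy
  labels <- sample(c("optimal", "disengaged"), n, TRUE, prob = c(0.7, 0.3))
  b <- binned_state_prob(feats, labels)
  global <- mean(labels == "optimal")
  ci <- 4 * sqrt(global * (1 - global) / min(b$bins$count))
  expect_true(all(abs(b$bins$optimal - global) < ci))
})

test_that("polynomial degree selection finds a noiseless parabola", {
  x <- seq(0.2, 1, length.out = 12)
  p <- pmax(0.05, 0.9 - 2.2 * (x - 0.6)^2)
  fit <- fit_optimal_pupil(make_binned(x, p, rep(200, 12)))
  expect_equal(fit$degree, 2)
  expect_equal(fit$optimal, 0.6, tolerance = 2e-3)

  # monotone increasing probabilities: argmax clamps to the data edge
  fit2 <- fit_optimal_pupil(make_binned(x, seq(0.1, 0.9, length.out = 12),
                                        rep(200, 12)))
  expect_equal(fit2$optimal, max(x), tolerance = 1e-9)

  expect_error(fit_optimal_pupil(make_binned(x[1:4], p[1:4], rep(200, 4))),
               "bins")
})

test_that("the optimum is recovered under binomial sampling noise", {
  set.seed(8)
  x <- seq(0.15, 0.95, length.out = 10)
  p_true <- pmin(0.95, pmax(0.05, 0.85 - 2.5 * (x - 0.55)^2))
  hits <- rbinom(length(x), 200, p_true)
  fit <- fit_optimal_pupil(make_binned(x, hits / 200, rep(200, 10)))
  expect_lt(abs(fit$optimal - 0.55), 0.05)
})

test_that("distance from the optimal pupil is centered and signed", {
  set.seed(9)
  pupil <- 0.55 + runif(5000, -0.2, 0.2)   # symmetric around the optimum
  feats <- data.frame(pupil = pupil)
  al <- align_to_optimal(feats, 0.55,
                         labels = rep(c("optimal", "disengaged"), 2500))
  expect_lt(abs(mean(al$distance)), 0.01)
  expect_gt(mean(al$abs_distance), 0.05)
  expect_equal(align_to_optimal(data.frame(pupil = 0.55), 0.55)$distance, 0)
  expect_named(al$by_state)
})

test_that("quadratic regression recovers generative coefficients", {
  set.seed(10)
  n <- 6000
  feats <- data.frame(
    pupil = rnorm(n), face = rnorm(n), locomotion = rnorm(n),
    pupil_sd10 = rnorm(n), face_sd10 = rnorm(n), locomotion_sd10 = rnorm(n),
    movement_index = rnorm(n), movement_index_sd10 = rnorm(n)
  )
  pupil_z <- (feats$pupil - mean(feats$pupil)) / sd(feats$pupil)
  target <- 1 - pupil_z^2 + rnorm(n, sd = 0.1)
  fit <- quadratic_state_regression(feats, target)
  expect_lt(abs(fit$coefficients[["pupil_sq"]] - (-1)), 0.1)
  expect_gt(fit$cv_r2, 0.5)

  # target independent of features: cross-validated r2 is negligible
  fit0 <- quadratic_state_regression(feats, rnorm(n))
  expect_lt(fit0$cv_r2, 0.02)

  # pure interaction target: only the interaction coefficient is non-null
  move_z <- (feats$movement_index - mean(feats$movement_index)) /
    sd(feats$movement_index)
  target_int <- pupil_z * move_z + rnorm(n, sd = 0.05)
  fit_int <- quadratic_state_regression(feats, target_int,
                                        measures = c("pupil",
                                                     "movement_index"))
  cf <- fit_int$coefficients
  expect_lt(abs(cf[["pupil_x_movement_index"]] - 1), 0.1)
  others <- cf[setdiff(names(cf), "pupil_x_movement_index")]
  expect_true(all(abs(others) < 0.05))
})

test_that("state-conditioned correlations separate coupled states", {
  set.seed(11)
  n <- 600
  labels <- rep(c("optimal", "disengaged"), each = n)
  pupil <- rnorm(2 * n)
  move <- c(2 * pupil[1:n] + 1,                 # perfectly coupled
            rnorm(n))                            # independent
  feats <- data.frame(pupil = pupil, movement_index = move)
  r <- state_conditioned_correlation(feats, labels)
  expect_equal(unname(r["optimal"]), 1, tolerance = 1e-12)
  expect_lt(abs(r["disengaged"]), 3 / sqrt(n))

  # groups below the minimum trial count are missing
  r2 <- state_conditioned_correlation(feats[1:5, ], labels[1:5])
  expect_true(is.na(r2["optimal"]))
})

test_that("variability change is aligned to optimal-state transitions", {
  st <- c("optimal", "disengaged")
  # constant variability: aligned change identically zero
  labels <- list(c(rep(2L, 20), rep(1L, 30), rep(2L, 20)))
  feats <- data.frame(session = 1, pupil_sd10 = rep(0.5, 70))
  out <- transition_aligned_variability(labels, feats, st)
  expect_true(all(out$entry$mean_change == 0))
  expect_true(all(out$exit$mean_change == 0))

  # variability halved during the optimal epoch
  sd10 <- c(rep(0.4, 20), rep(0.2, 30), rep(0.4, 20))
  out2 <- transition_aligned_variability(labels,
                                         data.frame(session = 1,
                                                    pupil_sd10 = sd10), st)
  expect_lt(out2$mean_entry_change, 0)
  expect_gt(out2$mean_exit_change, 0)

  # no optimal epochs: empty result with a warning
  expect_warning(
    out3 <- transition_aligned_variability(list(rep(2L, 50)),
                                           data.frame(session = 1,
                                                      pupil_sd10 = rep(1, 50)),
                                           st),
    "no optimal")
  expect_true(is.na(out3$mean_entry_change))
})
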