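# statehmm

Mice (and other animals) performing a sensory-discrimination task do not hold
a single strategy: they drift between minutes-long *performance states* —
optimal stimulus-guided responding, one-sided biases, selective avoidance, or
complete disengagement — even while the task itself stays constant. `statehmm`
is an R package for segmenting two-alternative choice behavior (with a
no-response option) into such discrete states and for relating those states to
arousal and uninstructed movement measured by pupil diameter, face motion
energy, and locomotion speed.

It is written for researchers analyzing head-fixed rodent decision-making
data, and for anyone who wants a tested, self-contained implementation of a
multinomial GLM-HMM with its surrounding analysis pipeline.

## The model

Each trial `t` presents a signed stimulus value `u_t` in `[-1, 1]` and the
animal chooses `y_t` in `{L, R, Nr}` (left lick, right lick, no response). A
hidden state `z_t` in `{1..K}` follows a Markov chain with a `K x K`
transition matrix `A` and an initial distribution `pi`. Given the state, the
choice is multinomial-logistic in the stimulus:

```
Pr(y_t = c | z_t = k, u_t) = exp(w_k,c * u_t + b_k,c) / sum_c' exp(w_k,c' * u_t + b_k,c')
```

so each state is a set of three psychometric curves. The `Nr` category is the
softmax reference (`w = b = 0`), which fixes the usual over-parameterization
without changing any probability. Fitting is by EM: exact forward-backward
smoothing in the E-step, closed-form transition/initial updates and
numerically maximized per-state weighted multinomial regressions in the
M-step, under either maximum likelihood or a MAP objective (Gaussian prior on
weights, variance 2; Dirichlet prior on transition rows, alpha 2). The number
of states is chosen by 5-fold cross-validation across sessions with random
restarts, taking the smallest `K` on the plateau of held-out log-likelihood.

Downstream, per-trial posteriors are thresholded at 0.8 into discrete labels
(below threshold = *indeterminate*), states are classified into six
stereotypes (optimal, disengaged, left/right bias, avoid left/right), and the
package provides the arousal analyses built on those labels: pre-stimulus
feature extraction (Savitzky-Golay conditioning, 1 kHz upsampling,
session-max pupil normalization, 10-trial rolling SD, combined movement
index), per-subject optimal pupil diameter from cross-validated polynomial
fits of optimal-state occupancy versus pupil, quadratic state-probability
regressions, state-conditioned pupil-movement correlations,
transition-aligned variability, and a permutation-calibrated RBF-SVM state
decoder.

A synthetic-experiment generator (`generative_config()`,
`simulate_experiment()`) produces complete sessions — hidden state sequences,
choices, and state-coupled physiological traces — with known ground truth, so
the whole pipeline is testable end to end.

## Worked example

```r
library(statehmm)

cfg <- generative_config(n_sessions = 5, trials_per_session = 300, seed = 11)
sim <- simulate_experiment(cfg)
trials <- lapply(sim$sessions, `[[`, "trials")

fit <- em_fit(trials, K = 3, seed = 12, restarts = 3)
#> GLM-HMM fit: K = 3, objective = -779.208, 8 EM iterations (converged)

map <- classify_stereotypes(fit$params)
#> State stereotypes: 1=disengaged, 2=bias_left, 3=optimal

labels <- lapply(trials, function(tr) discretize(forward_backward(fit$params, tr)))
dwell_stats(labels, map)
#> State occupancy:
#>   optimal       42.2%
#>   disengaged    21.5%
#>   bias_left     33.5%
#>   indeterminate 2.8%
#> Median transition duration: 3 trial(s)

feats <- trial_features(sim$sessions)
slab <- unlist(lapply(labels, stereotype_labels, stereotypes = map))

fit_optimal_pupil(binned_state_prob(feats, slab, "pupil"))
#> Optimal pupil fit: degree 4, optimal diameter 0.574

round(state_conditioned_correlation(feats, slab), 2)
#>    optimal disengaged  bias_left
#>       0.04       0.80       0.59

decode_state(feats, slab, "disengaged", n_shuffles = 200, seed = 13)
#> State decoder optimal vs disengaged: accuracy 100.0%, z = 3.9 (n = 320/class)
```

The generator placed the optimal state at a normalized pupil diameter of
0.55 with weak pupil-movement coupling (0.1) in the optimal state and strong
coupling (0.8) while disengaged; the fitted pipeline recovers the optimum
(0.574), the coupling pattern (0.04 vs 0.80), and decodes state from
physiology alone far above its permutation null.

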