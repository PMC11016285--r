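---
title: "Segmenting decision-making behavior into performance states and relating them to arousal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting decision-making behavior into performance states and relating them to arousal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statehmm)
```

## The problem

During long sensory-discrimination sessions, head-fixed mice alternate
between qualitatively different ways of doing the task: stretches of
accurate, stimulus-guided responding; stretches of licking one port
regardless of the stimulus; stretches of answering one stimulus category and
ignoring the other; and stretches of not responding at all. Averaging over
these regimes blurs every downstream analysis. `statehmm` models the regimes
explicitly, as discrete hidden states, and then asks how externally
observable physiology — pupil diameter, face motion energy, locomotion
speed — relates to them.

## The model and its assumptions

The observation on trial $t$ is a choice $y_t \in \{L, R, Nr\}$ given a
signed stimulus value $u_t \in [-1, 1]$ (for tone clouds, the right-octave
minus left-octave tone proportion; for Gabor patches, the normalized angular
distance from 45° signed by the assigned side). A hidden state
$z_t \in \{1, \dots, K\}$ evolves as a first-order Markov chain (transition
matrix $A$, initial distribution $\pi$), and the emission of state $k$ is a
three-category multinomial logistic model,
$$
\Pr(y_t = c \mid z_t = k, u_t) =
\frac{\exp(w_{k,c} u_t + b_{k,c})}{\sum_{c'} \exp(w_{k,c'} u_t + b_{k,c'})},
$$
i.e. three psychometric curves per state. Assumptions worth keeping in mind:
the chain is time-homogeneous within and across sessions (one parameter set
per subject), transitions are not stimulus- or outcome-driven, each session
is an independent chain starting from $\pi$, and the GLM input is the scalar
stimulus value plus a bias (the code accepts $d$-dimensional inputs should
richer designs be needed).

**Identifiability.** A three-category softmax is over-parameterized: adding
any constant to all logits leaves probabilities unchanged. We pin the
no-response category as the reference ($w_{k,Nr} = b_{k,Nr} = 0$ in every
state). Any other gauge yields identical probabilities — a property the test
suite verifies against an unconstrained softmax fit. Likelihoods are also
invariant to permuting state labels; recovery analyses therefore align
states to a reference by the weight-distance-minimizing permutation
(`align_states()`).

## Fitting

`em_fit()` maximizes the log-likelihood (MLE) or log-posterior (MAP) by EM:

* **E-step**: exact forward–backward smoothing per session, in log space
  (no underflow at thousands of trials and $K = 7$), implemented in C++.
* **M-step**: $A$ from expected transition counts, plus
  $\alpha - 1$ Dirichlet pseudo-counts under MAP ($\alpha = 2$); $\pi$ from
  expected initial-state counts (or held uniform via `init_prob_mode`);
  per-state GLM weights by BFGS on the posterior-weighted multinomial
  log-likelihood with analytic gradients, warm-started from the previous
  iterate, with a Gaussian ridge ($\sigma^2 = 2$) under MAP.

Because every M-step component does not decrease its part of the expected
complete-data objective, the EM objective is non-decreasing; the
implementation asserts this at $10^{-8}$ every iteration and the tests check
it across seeds and prior modes. Convergence is declared when the objective
improves by less than `tol` (default $10^{-4}$; the cross-validation scan
uses $10^{-3}$) or after `max_iter` iterations (default 300). BFGS stalls
once the objective is flat to $\sim 10^{-10}$, which can leave weights
$\sim 10^{-6}$ from the optimum; after the EM loop each state's GLM gets a
short Newton polish (finite-difference Hessian over the analytic gradient),
one more generalized M-step that brings the $K = 1$ fit within $10^{-8}$ of
a directly optimized multinomial-logistic MLE.

Random initialization draws weights from $N(0,1)$, a sticky transition
matrix (0.9 diagonal plus noise), and a uniform $\pi$; `restarts` controls
the number of seeded initializations and the best final objective wins.

## Choosing the number of states

`select_num_states()` shuffles sessions with a fixed seed, splits them
round-robin into 5 folds, and scores each candidate $K$ by held-out
log-likelihood per trial, fitting best-of-`restarts` models on the training
sessions. The "maximum of the plateau" is operationalized as the smallest
$K$ within `plateau_tol` (0.002 nats/trial) of the maximum — enough, in the
recovery experiments below, to select the generative $K$ for both 1- and
3-state truths in 10/10 seeded replicates at 10 sessions of 300 trials with
3 restarts. The final subject model is refit to all sessions by MLE.

`predict_choices()` measures cross-validated choice-prediction accuracy: in
rotating folds, contiguous 20% blocks of each session are withheld, a model
is trained on the flanking segments of every session (each segment an
independent chain), and a test trial is predicted by filtering the state
belief forward over the trials before its block, propagating it through $A$
across each withheld trial in the gap, taking the argmax state, and
predicting that state's argmax choice category at the trial's stimulus.
Ties in either argmax break toward the lowest index. One model is trained
per trial-block fold rather than reusing the session-level CV models, so
the prediction never sees its own block during training.

## From posteriors to stereotyped states

Trials are assigned to their maximum-posterior state when that posterior
reaches 0.8 (inclusive), otherwise they are *indeterminate*
(`discretize()`). Fitted states are mapped onto six stereotypes by their
response profile at the easiest stimuli ($u = \pm 1$): disengaged if
$\Pr(Nr) \ge 0.5$ on both sides; optimal if the correct lick reaches 0.5 on
both sides; left/right bias if one lick direction reaches 0.5 on both sides;
avoid-right/left if one side is answered correctly while the other side's
no-response reaches 0.5. The 0.5 thresholds are this package's construction
(the categories are usually described qualitatively); profiles matching no
rule fall back to the nearest idealized profile by total-variation distance,
so the map is total. `dwell_stats()` computes occupancy fractions, epoch
dwell times (never merged across session boundaries), and transition
durations — indeterminate runs flanked by two discrete states; edge runs
count as indeterminate occupancy but not as transitions.

## Physiological features

`trial_features()` runs the conditioning pipeline per session: pupil gaps
shorter than 200 ms (strict) are linearly interpolated and longer gaps stay
masked; each trace is smoothed with a second-order Savitzky–Golay filter
(500 ms window for pupil, 200 ms for face and locomotion) at the native
rate and then upsampled to 1 kHz by linear interpolation (smoothing before
upsampling is this package's ordering choice). Conditioned locomotion is clamped at zero because polynomial
smoothing undershoots at sharp movement onsets. Pupil is normalized to its
session maximum. The per-trial value of each measure is the 1 kHz sample
immediately *strictly before* stimulus onset; rolling variability (`sd10`,
`cv10`) uses the sample SD over the previous 10 trials, requires at least 3
past values (earlier trials are missing, never padded), and never touches
the current trial — perturbing trial $t$ cannot change features at or
before $t$. The movement index z-scores face motion energy and locomotion
across all supplied trials of a subject (not per session, so the index is
comparable across sessions) and sums them; the same construction applies to
the rolling SDs. `cv10` is computed and exported but the downstream analyses
use `sd10`.

## Arousal analyses

`binned_state_prob()` bins trials into 10 quantile bins of a measure and
reports per-bin stereotype proportions (bins under 20 trials are flagged and
excluded from fits). `fit_optimal_pupil()` scans polynomial degrees 1–6 with
5-fold cross-validation over bins and picks the degree at the elbow of the
test-$r^2$ curve, defined here as the smallest degree already capturing at
least 90% of the total cross-validated $r^2$ gain over the linear fit. This
formulation is robust to the non-monotone $r^2$ curves that sharply peaked
state–pupil profiles produce at high degrees (a naive
"first-small-increment" rule can stop at degree 1 when the curve dips before
it rises). The final fit is count-weighted over all usable bins, and the
optimal pupil diameter is the argmax of the fitted curve restricted to the
bin-supported range — evaluating a high-degree polynomial outside that range
is pure extrapolation and can invent spurious maxima at the data edge.

`quadratic_state_regression()` regresses a stereotype's per-trial posterior
probability (soft targets by default; hard indicators optional) on z-scored
measure values and rolling SDs, squared z-values, and pairwise products of
z-values. Squared and interaction columns are built from the z-scored values
but not re-standardized, so a generative coefficient of $-1$ on
$\mathrm{pupil}_z^2$ is recovered as $-1$. `state_conditioned_correlation()`
computes Pearson correlations between pre-stimulus pupil and the movement
index per stereotype (at least 10 trials, per-trial values rather than
continuous traces). `transition_aligned_variability()` extracts a rolling-SD
feature in a ±10-trial window around each entry into and exit from the
optimal state, subtracts the window-start baseline, and averages across
transitions, then sessions; windows crossing session edges are dropped. The
window half-width is a package choice. Note that a rolling SD taken across a
state boundary mixes the *level* difference between states with
within-state variability: for a measure whose state means differ strongly
(pupil, by design of the inverted-U), the aligned curve spikes at the
transition before settling; locomotion, whose state means coincide, isolates
the variability change cleanly.

## State decoding

`decode_state()` discriminates optimal-state trials from one other
stereotype with an RBF-kernel SVM on six features (three measures × value
and `sd10`), or four features in the movement-index variant. Classes are
balanced by seeded subsampling (optionally capped by `max_per_class`),
features standardized with training-fold statistics only, accuracy averaged
over 5 stratified folds, and significance z-scored against classifiers
retrained on training-label-permuted surrogates. The kernel hyperparameters
are free choices here: we use cost 1 and the median
pairwise-distance heuristic for the kernel width, both configurable.
`feature_contribution()` instead permutes the features *outside* a kept
subset within the training folds (test folds untouched), isolating where
the class signal lives; both surrogate modes are thus available explicitly.
The permutation z-scores are approximately, not exactly, standard normal
under the null: the shuffle distribution conditions on the realized test
labels, so the marginal spread of the empirical accuracy slightly exceeds
the shuffle spread (measured SD ≈ 1.3 at 50 trials/class). The calibration
test checks the distribution against a standard normal by KS at
$\alpha = 0.01$ and bounds the chance-level |z| at 2.

## The synthetic-experiment generator

`generative_config()` encodes the study conditions: 1.2 s stimuli,
inter-trial intervals uniform on $5 \pm 2$ s (only the range is specified
by the task; lick-resets of the ITI are not simulated), stimulus values
on the six-value grid $\{\pm 1, \pm 0.6, \pm 0.2\}$ (three difficulties per
side; the visual grid maps angles $\{0, 18, 36, 54, 72, 90\}°$ through
$|a - 45|/45$), sessions of a few hundred trials, and a sticky 3-state
ground truth (diagonal 0.98) with optimal, disengaged, and left-biased
states. Choices are drawn from the true state's emission model; outcomes
follow the task rule (correct-side lick = hit).

Physiology is generated per trial: a standard-normal movement factor drives
face motion energy and locomotion, and the pupil deviate correlates with it
by the state's `pupil_move_corr`; targets are the state mean plus the state
SD times these deviates. Default coupling places the optimal state at
normalized pupil 0.55 with halved SDs and weak coupling (0.1), the
disengaged state at pupil 0.88 with strong coupling (0.8), and the biased
state at 0.30 with coupling 0.6; face means (0.48/0.43/0.44) and locomotion
means (0.14 m/s everywhere) follow the magnitudes reported for real
sessions. Between onsets the traces relax geometrically (AR coefficient
`persistence`, default 0.8 at 30 Hz) toward the upcoming target, hold the
target through the stimulus window so that the *smoothed* pre-stimulus
sample still carries the drawn target, and are clipped to physical ranges
(clipping slightly truncates the moments of states near a bound — the
disengaged pupil at 0.88 loses a few percent of its upper tail, which is
the main reason recovered disengaged-state correlations sit ~0.05–0.1 below
the configured 0.8).

What the generator deliberately does not emulate: stimulus-driven or
outcome-driven state transitions, slow nonstationarity across sessions,
pupil light reflexes and blinks beyond gap masking, video frames (face
motion energy is generated directly as a trace), licking dynamics, and
training-stage structure. Passing the round-trip tests therefore shows that
the pipeline recovers the statistical structure it models — not that real
data satisfy that structure.

## Numerical choices and degenerate inputs

Log-space inference guards against underflow with max-shifted
log-sum-exp; zero transition probabilities are representable ($-\infty$
logs). Zero rows in expected transition counts fall back to uniform.
Zero-variance inputs to the movement index raise an error (z-scores are
undefined) rather than silently producing NaN. Discretization uses an
inclusive threshold ($\gamma \ge 0.8$). Session-inclusion filters follow
the stated criteria (≥100 rewards, ≥20% of rewards at each port, ≥10
surviving sessions per subject, stages 5–6 when a stage label exists;
rewards are counted as hit trials and port shares over hits by reward
port). `filter_sessions()` is idempotent and logs every exclusion with its
reason.

## Problem sizes used by the tests and the acceptance script

Parameter recovery runs at 10 sessions × 400 trials (transition diagonal
recovered within ±0.03, per-state GLM parameter vectors within 15% relative
L2 after alignment — the generative disengaged state has zero stimulus
weights, so element-wise relative error is undefined and the vector norm is
the meaningful scale). The state-count recovery experiment runs 10 seeded
replicates per truth at 10 sessions × 300 trials with 3 restarts; the
acceptance script reports hit rates over 5 replicates per truth and caps
the decoder at 300 trials per class. These sizes are the package's chosen
benchmark conditions; all of them are plain function arguments.

## Known limitations

* Reading the deposited NWB session files directly is not supported; the
  canonical interchange is the tabular dialect documented in
  `read_sessions()`, to which NWB exports can be converted externally.
* The model assumes discrete states; slow continuous drifts in strategy are
  represented, at best, as indeterminate stretches between states.
* Transitions are not input-driven, and emissions see only the scalar
  stimulus value (no choice history, no bias drift within a state).
* The stereotype map's 0.5 thresholds are a convention; profiles near the
  rule boundaries are classified by nearest idealized profile, which can be
  sensitive for genuinely intermediate states.
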