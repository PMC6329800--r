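---
title: "Models and statistics behind featrpe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and statistics behind featrpe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(featrpe)
```

featrpe implements the computational chain of a feature-based
reversal-learning experiment: a family of dimension-weighted
reinforcement-learning (RL) models that turn choice sequences into trial-wise
reward-prediction errors (RPEs), a synthetic electrophysiology module that
generates spike trains with planted encoding structure, a sliding-window
correlation classifier that labels neurons as carrying outcome, nonspecific
RPE, or feature-specific RPE signals, and the population statistics built on
those labels (latency distributions, prevalence bootstraps, color-tuning
indices, attention-transfer contrasts, and waveform-based cell typing). This
vignette explains each model, the tunable parameters, and the design choices
made where the design was genuinely open.

## The task

Two peripheral stimuli differ on three dimensions — color, location, and
motion direction — with two feature values each. Only color predicts reward:
within a block one color is always rewarded, and the association reverses
unannounced once the running accuracy over the last 12 trials reaches 90%
(checked from trial 30; blocks are capped at 100 trials). Location and motion
are re-randomized every trial. `generate_session()` simulates this schedule
around any choice agent; `agent_rl()` wraps an RL model as the behaving
agent. Event times (stimulus onset, color/motion onset in random order,
dimming, outcome) are drawn from the configured ranges of `task_config()`.

Whether a block was *learned* is decided by an ideal-observer criterion.
`learning_trial()` implements a standard state-space learning-curve
construction: the latent probability-correct follows
a reflected Gaussian random walk (sd 0.1/trial) on a 99-point grid with a
uniform prior, outcomes are Bernoulli emissions, and forward-backward
smoothing gives a posterior per trial. The learning trial is the earliest
trial whose lower one-sided 95% credible bound exceeds chance (0.5 for the
binary choice) and stays above chance for the rest of the block. Other
ideal-observer variants exist; all downstream analyses depend only on the
learned/unlearned block split this one produces, and the construction is
stated in full so it can be reproduced exactly.

## The RL model family

All models maintain one value per feature (six values), initialized at
`v0 = 0.5`, the unbiased prior under deterministic binary reward. A
stimulus's value is the weight-averaged value of its features,

$$V(s) = \sum_d w_d\, V_{f_d(s)},$$

with dimension weights $w_d \ge 0$, $\sum_d w_d = 1$. Choices are softmax in
the two stimulus values with selection noise $\beta$. After the outcome
$R \in \{0, 1\}$, the model computes $\mathrm{RPE} = R - V(\text{chosen})$
and updates the chosen stimulus's features,

$$V_f \leftarrow V_f + \eta\, g_d\, \mathrm{RPE},$$

where the gate $g_d$ is 1 or the dimension weight, depending on the variant:

| variant | value aggregation | update gate | decay | weights | free parameters |
|---|---|---|---|---|---|
| F-NS | uniform (1/3) | 1 | — | fixed | $\eta, \beta$ |
| F-S | color only | 1 (color only) | — | — | $\eta, \beta$ |
| F-DW | learned $w_d$ | $w_d$ | — | learned | $\eta, \beta, \phi$ |
| F-Dec | uniform (1/3) | 1 | yes | fixed | $\eta, \beta, \omega$ |
| F-DW-Dec | learned $w_d$ | $w_d$ | yes | learned | $\eta, \beta, \phi, \omega$ |

Decay variants pull the *nonchosen* stimulus's feature values back toward
the prior, $V_f \leftarrow \omega V_f + (1 - \omega) v_0$ ($\omega = 1$
means no decay). Weighted variants track each dimension's predictiveness
through the separation of its two feature values,
$s_d = |V_{f_1,d} - V_{f_2,d}|$, moving the weights toward the normalized
shares at rate $\phi$ and renormalizing. The weighting rate is called $\phi$
throughout; some figure legends in the attention-weighted RL literature
label the same quantity $\alpha$.

These exact update forms (linear aggregation, softmax, attention-gated
delta rule, share-of-predictiveness weight update, convex decay toward the
prior) are the package's declared model family — the standard constructions
in the attention-weighted RL literature. All quantitative checks are
self-consistency checks: data are simulated from these equations and refit
with them.

State is reset at session boundaries only — reversals are uncued to the
model, so no reset happens at block boundaries.

### Fitting, cross-validation, model comparison

`fit_rl()` minimizes the negative log likelihood of the observed choices
(probability floor $10^{-9}$) with bounds $\eta, \phi, \omega \in [0, 1]$
and $\beta \in [0, 20]$. The likelihood surface of the four-parameter
variant has shallow local basins, so every fit is multi-start: a fixed
two-level grid over the free parameters (16 starts for F-DW-Dec) plus
optional random starts, each polished by a simplex warm-up followed by
bounded L-BFGS-B. The surface is flattest in $\phi$ — once the weights have
converged to the color dimension, a wide range of weighting rates produces
nearly the same choice probabilities — which is why single-dataset estimates
of $\phi$ scatter more than the other parameters and recovery is summarized
by the median over replicate simulate-and-refit experiments
(`recover_parameters()`, 10 replicates of 50 sessions with ~9 blocks each).

`cross_validate_rl()` splits by block (80/20, 50 repetitions by default) to
avoid trial-level leakage; the model state always evolves over the full
trial sequence, and only the trials of the respective block set are scored,
so removing blocks never breaks the state dynamics. `compare_models()`
reports $k$, NLL, $\mathrm{AIC} = 2k + 2\,\mathrm{NLL}$ and mean held-out
log likelihood.

## Synthetic spike trains

`simulate_neuron()` produces event-locked inhomogeneous Poisson spikes:
baseline rate plus planted signals, each adding `gain * regressor` Hz within
a window `[event + latency, event + latency + duration)` on trials matching
an optional feature condition. Regressors mirror the analysis definitions:
outcome (0/1), RPE on correct trials (pRPE), minus RPE on error trials
(nRPE; firing grows as the RPE becomes more negative), absolute RPE (uRPE,
"surprise"), and a transfer signal whose color-onset gain scales with
$1 - |\mathrm{RPE}_{n-1}|$ after preferred-color choices. All contributions
are nonnegative, so superposing independent Poisson processes is exact.
Default baselines are log-normal around 5 Hz (sd 0.4 on the log scale),
essentially always above the 0.5 Hz inclusion floor. Waveforms are biphasic
two-Gaussian templates at 40 kHz sampling, 64 samples (1.575 ms — long
enough to contain the broad template's repolarization), with
trough-to-peak 0.175 ms (narrow) versus 0.5 ms (broad).

What the generator does *not* emulate: firing-rate autocorrelation beyond
the planted windows, correlated noise across neurons, bursting and
refractoriness, drift, and spike-sorting contamination. Passing tests
therefore demonstrate that the analysis chain recovers planted structure
under Poisson variability, not that it is robust to every property of real
recordings.

## The encoding classifier

Rates are counted in 200 ms windows stepped by 25 ms from −500 to +1500 ms
around the outcome (73 windows; the step is configurable — 25 ms is the
default, so that four consecutive windows span 0.1 s).
Windows are labelled by their centers; a window is *post-outcome* when it
lies entirely at or after the event and *pre-outcome* when entirely before
it; the seven straddling windows belong to neither run rule.

A neuron is included if its feedback-epoch (0–1.5 s) rate is at least
0.5 Hz and at least 40 usable trials exist — choice trials of learned
blocks with an RPE. Each included neuron is then tested per signal type:
Spearman correlation of rate with RPE on correct trials (pRPE, positive
correlations count), with RPE on error trials (nRPE, negative correlations
count; the opposite convention sits behind the `nrpe_positive` flag,
default off), and partial rank correlation of rate with |RPE| controlling a
±1 outcome covariate (uRPE). Correlations require at least 15 trials;
p-values use the t approximation, with a label-permutation option for small
samples. Encoding is declared when at least 4 consecutive post-outcome
windows are significant (p < 0.05, required sign) while no run of more than
2 significant same-sign windows precedes the outcome; the reported window
is the first qualifying run. No multiple-comparison correction is applied
across windows — the consecutive-run rule is the control, and the package
measures and documents its actual operating characteristics (below).

Feature-specific encoding of a dimension splits trials by the chosen
feature value, computes both maps, and compares them per window with the
Fisher z-test,

$$Z = \frac{z_1 - z_2}{\sqrt{1/(N_1 - 3) + 1/(N_2 - 3)}},\qquad
z_i = \operatorname{atanh}(r_i),$$

flagging the dimension when at least 4 consecutive post-outcome windows
have $|Z| > 1.96$ *and* the encoding criterion holds for at least one
feature value; the z-run must overlap the encoding run by at least one
window — the weakest coupling consistent with requiring both. The pre-outcome exclusion applies
to the encoding criterion only. The preferred feature is the value with the
qualifying encoding (larger peak |R| decides when both qualify). For
comparison analyses a neuron counts as nonspecific for a signal only when
it is not feature-specific for that signal, keeping the two populations
disjoint.

A consequence worth stating plainly: the 200 ms windows stepped by 25 ms
overlap by 87.5%, so a chance excursion persists across roughly eight
neighbouring windows and 4-window runs are *not* rare under the null even
though the per-window test is exactly calibrated (~5%). Measured on pure
Poisson neurons, the per-signal nonspecific false-flag rate is about
6–10% and about a third of noise neurons acquire some feature-specific
flag across the nine (signal × dimension) tests. This is a structural
property of the run rule itself, not of this implementation; it should be
kept in mind when interpreting prevalence numbers.

## Population statistics

Latency distributions pool encoding-window times over neurons — first-run
windows only for latency comparisons, all significant windows for the
population histograms — and are compared by two-sample Kolmogorov–Smirnov
tests with Bonferroni–Holm correction plus companion rank-sum tests. The
"25% crossing" (earliest time at which the normalized cumulative sum
reaches 0.25) is compared between groups by permuting neurons (500
permutations, p = (b+1)/(n+1) so p is never exactly zero).

The prevalence test asks whether one dimension's feature-specific encoding
is more common than expected from all feature-specific neurons regardless
of dimension. It is operationalized as an exchangeability null: each of 10,000
replicates reassigns every flagged (neuron, dimension) unit a dimension
drawn uniformly from the three, and a dimension is flagged when its
observed proportion exceeds the 95th percentile of the null proportions.
The color-tuning index
$I_{col} = (P_{col} - (P_{loc} + P_{mot})/2) / (P_{col} + P_{loc} + P_{mot})$
summarizes color dominance per area (range −0.5 to 1); area differences are
tested against 10,000 area-label shuffles with a two-sided 95% interval.

The attention-transfer analysis takes each color-specific RPE neuron's 25%
lowest- and highest-|RPE| trials (within the trial class matching its
signal type; ties broken by trial order), moves to the next trial when it
stays within the same block, and computes the normalized color-onset rate
change $\Delta = (r_{post} - r_{pre}) / (r_{post} + r_{pre})$ with
pre = [−0.5, 0) s and post = [0, 0.5) s around color onset (both
configurable; $\Delta = 0$ when both rates are 0). This index is the
standard normalized form with range [−1, 1]. Paired
t-tests compare low- versus high-RPE $\Delta$ within preferred and
nonpreferred previous-color conditions, with Hedges' g effect sizes.

Cell typing standardizes two waveform features (cortical: trough-to-peak
duration and time to 25% repolarization; striatal: trough width at half
amplitude and the initial slope of valley decay over 0.1 ms — both
thresholds configurable), projects onto the first principal component, and
splits at
the kernel-density antimode between the two largest modes (bandwidth
0.2 × sd so duplicated inputs split identically; a valley shallower than
80% of the smaller mode is treated as unimodal, triggering a median split
and a low-confidence flag). Striatal units farther than 2 SD from both
cluster centroids stay "unidentified". Enrichment of an encoding property
in a cell class is a 2×2 chi-square without continuity correction, with the
phi coefficient as effect size.

## Numerical and design notes

* Softmax is computed with max-subtraction; likelihood probabilities are
  floored at $10^{-9}$.
* The compiled forward pass (Rcpp) is verified against a pure-R reference
  implementation to ~1e-16 on every variant.
* Correlations of constant rate vectors are reported as $R = 0$ (no
  encoding) rather than NA.
* Randomization p-values use the (b+1)/(n+1) estimator; all resampling is
  seed-deterministic and the seeds are recorded in the run report.
* Dimming order (target before/after/with distractor) affects event timing
  only and is folded into the dimming-time draw; fixation breaks and other
  non-choice errors are not simulated because the analyses exclude them.

## Problem sizes used by the tests

The packaged experiments run at desk scale: parameter recovery uses 10
replicates of 50 sessions × 9 blocks (~15,000 trials per replicate);
classifier calibration uses 500 pure-noise neurons and 40 planted neurons
on one 9-block session (~270 trials, ~100 correct trials per color split);
the z-test calibration uses 10,000 null replicates at N = 100 per group.
The planted feature-specific neurons used for the sensitivity check carry a
14 Hz-per-unit-RPE gain on a 3 Hz baseline — a strong but realistic outcome
response (3 → 17 Hz at unit RPE); the gain–sensitivity curve measured at
gains 6/10/14 Hz rises from ~0.3 to ~0.9, so weaker modulations are
detected at proportionally lower rates, as the conservative compound
criterion implies.

## Known limitations

The model equations are a declared family, so quantitative validation is
by self-consistency (simulate-and-refit) rather than against external
fitted values. The synthetic generator omits several properties of real
spike trains (see above). The ideal-observer criterion and the prevalence
bootstrap are specific operationalizations among several reasonable ones.
Finally, the consecutive-window rule has a materially higher false-positive
rate than its per-window level suggests (overlapping windows), which this
package measures and reports rather than hides.
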