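---
title: "Shift and drift: modelling the timing of social information in confidence judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shift and drift: modelling the timing of social information in confidence judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

When people judge a perceptual stimulus and then see another person's
choice before committing to their own judgment, the social information can
enter the decision process in two qualitatively different ways. It can
produce a one-time, *instantaneous shift* of the accumulated evidence
toward the indicated option — the update a Bayesian observer would make.
Or it can act as a *continuous drift*, biasing the ongoing accumulation
for as long as deliberation continues. The two mechanisms are empirically
separable through timing: a pure shift predicts that early and late
social information have identical effects, while a drift predicts that
earlier information, which has more time to act, sways judgments more.

`socialdrift` implements the full analysis chain for this question on a
two-alternative color-discrimination task with an 11-point confidence
scale: balanced within-subject trial schedules, a generative simulator,
preprocessing with incentive-compatible scoring and subject exclusions, a
hierarchical Bayesian evidence-accumulation model with both social terms,
model comparison over all eight shift/drift variants, and ordered-probit
signal-detection analyses of discrimination ability.

# The task and its schedule

Each session has 120 trials in 20 blocks of six. A trial shows a bicolored
square for 1 s (easy: 51.5% dominant color; hard: 50.5%, metadata only —
stimuli are not rendered), then a 4 s deliberation phase during which the
choice of a previous participant may appear, then a judgment prompt with a
response window (2 s in Experiment 1, 3 s in Experiment 2). Judgments use
an 11-point scale from "100% confidence in blue" through "50%" to "100%
confidence in orange"; category `j = 6` is the undecided midpoint.

Each block contains two early-social trials (nominal onset 750 ms into
deliberation), two late-social trials (3250 ms), one no-social trial, and
one short (1 s deliberation) filler trial that keeps attention up and is
excluded from every analysis. Correct and wrong social information are
allotted 28 and 12 trials per timing, so social information is correct on
exactly 70% of social trials. Onsets get continuous uniform jitter of
±250 ms. Difficulty-by-color cells are exactly balanced within every
treatment (7/3/5 trials per cell for 28-, 12-, and 20-trial treatments).
`build_trial_schedule()` is a pure function of its configuration
(including the seed); only trial order within blocks is randomized, which
already spreads treatments approximately evenly across the session, so
block order is kept sequential.

In Experiment 1 the social cue stays visible until the end of
deliberation; in Experiment 2 it is shown for 500 ms at either onset. The
model below deliberately ignores display duration: the social drift runs
from onset to judgment in both designs, which is exactly the assumption
the two-experiment comparison is meant to probe.

# The generative model

Let `DT` be the time from stimulus onset to the judgment and `ST` the time
from social-information onset to the judgment (0 when absent), both in
seconds. With `col` the dominant color (+1 orange, −1 blue) and `λ` the
validity of the social information (+1 correct, −1 wrong), the latent
evidence at judgment time is normally distributed with mean

```
E(L) = τ·col + δp·DT + (δs·ST + γ)·λ          (correct-option axis)
var(L) = σ·DT,  σ = 1
```

where `δp` is the personal drift (`δ_easy` or `δ_hard` by difficulty),
`δs` the social drift, `γ` the instantaneous social shift, and `τ` a color
bias. The diffusion scale `σ` is fixed at 1, which sets the unit of the
evidence axis, as is standard in accumulation models. The model predicts
confidence judgments only — the judgment time is set by the task, so no
response-time likelihood is needed.

Responses live on the color axis (blue to orange). Multiplying the mean
above by `col` (note `col² = 1`) gives the equivalent color-axis mean

```
E(L_color) = τ + δp·DT·col + (δs·ST + γ)·col·λ
```

which is the form the simulator and likelihood use, because the observed
category `j` is a color-scale response. Ten criteria `c1 < … < c10`,
mirror-symmetric about zero (`c_k = −c_{11−k}`, so five free positive
increments), cut the axis into the 11 categories, and

```
P(j) = Φ((c_j − E)/√var) − Φ((c_{j−1} − E)/√var)
```

with `c_0 = −∞`, `c_11 = +∞`. Symmetry of the criteria makes the
correct-axis and color-axis formulations exactly equivalent; it encodes
the assumption that the psychological width of, say, "70%" is the same for
correct and wrong responses. A useful mirror identity follows: relabeling
the two colors (negating `col` and `τ`, which also flips the socially
indicated color) maps `P(j)` onto `P(12 − j)`; the test suite checks this
exactly.

The timing dichotomy is a closed-form property of the mean: with `δs = 0`
the predicted category distribution is identical for early and late
onsets, and with `δs > 0` the early−late difference in mean evidence is
exactly `δs·(ST_early − ST_late)`.

## Decision and social times

`DT = 1 s (stimulus) + deliberation + response latency` and
`ST = (deliberation − onset) + response latency`: both run to the moment
of judgment, with the realized onset including jitter. The 500 ms display
of Experiment 2 does not truncate `ST` (see above).

# The synthetic-data generator

The generator is the package's stand-in for the two experiments: all
tests and the acceptance analyses run on data it produces, so its defaults
are the study conditions.

* **Subject parameters** are drawn from normal population distributions.
  The default population means are the Experiment-1 population-level point
  estimates: `δ_easy = 0.90` evidence units/s, `δs = 0.18`/s, `γ = 2.41`,
  `τ = 0`. The hard-trial drift is not separately reported; the default
  `δ_hard = 0.45` (half the easy drift) produces the qualitatively correct
  difficulty effect. Population SDs (0.35, 0.30, 0.12, 1.0, 0.3) are
  chosen as realistic between-subject spreads of the same order as the
  means; nothing downstream is sensitive to their exact values.
* **Criteria** default to five increments of 1.75 evidence units, matching
  the reported spacing of roughly 1.5–2 units between criteria; they are
  shared across subjects.
* **Response latencies** follow a lognormal law truncated at one second
  past the response window; responses beyond the window are kept but
  flagged late. The lognormal location is solved (by `uniroot`) so that
  the mean of *in-window* latencies is 1.1 s (Experiment 1) or 1.3 s
  (Experiment 2), because the analyzed datasets then place judgments on
  average 3.1 s and 3.3 s after social-information onset — the quantity
  through which the drift's total adjustment (`δs × mean ST ≈ 0.56` and
  `0.46`) is reported. The scale parameters (sdlog 0.4 and 0.5) give
  roughly 5% and 3% late responses, matching the reported late shares.
* **Pathological subjects** can be injected for exclusion testing:
  always-100% responders, below-chance responders, chronic late
  responders, and miscalibrated responders (more confident when wrong).
  Ground-truth labels travel with the dataset so preprocessing tests are
  self-verifying.

What the generator does *not* emulate: sequential dependencies between
trials (the model is trial-independent), pixel-level stimuli, attention
lapses, and any systematic relation between latency and accuracy. Passing
tests therefore certify the implementation and the statistical machinery
on data that satisfy the model's assumptions; they do not certify the
model against real behavioral data. Simulations at the default truth also
produce higher overall accuracy than human participants showed — the
point estimates imply strong evidence extraction, and no attempt is made
to degrade them toward empirical accuracy levels, since no empirical
quantity downstream depends on it.

# Preprocessing

Judgments are scored with the Brier-based rule
`points = 100·[1 − (correct − conf)²] − 75`, which is proper: expected
points are maximized by reporting one's true probability of being
correct. The bonus is $0.20 per 100 points with a guaranteed $1 below 500
points. Subjects are excluded if any of the following trigger: more than
90% of trials at 100% confidence; average accuracy below 50% (undecided
50% judgments do not count toward accuracy); more than 10 late responses
(counted over all trials including fillers; the protocol leaves this
ambiguous, so the choice is stated here); strictly higher mean
confidence when wrong than when correct; or a self-reported display
glitch (honored as a pass-through flag only). Trial-level filters are
analysis-specific: accuracy analyses drop fillers and 50% judgments, the
accumulation model drops fillers and late trials, the ordinal analyses
drop fillers only.

# Fitting: slice-within-Gibbs MCMC

The hierarchical posteriors are sampled with a purpose-built
slice-within-Gibbs scheme implemented in C++ (univariate slice updates
with stepping-out for subject-level parameters, population SDs, criteria
and thresholds; conjugate normal draws for population means). Because the
social shift and the social drift trade off along `γ + δs·ST` — the
likelihood constrains mainly their combination at typical social times —
the sampler adds dedicated Metropolis exchange moves that slide subject
and population values along this ridge (trading `δs` against `γ` at the
subject's, respectively the sample's, mean `ST`), which raises the
effective sample size of the social-drift mean by an order of magnitude
at no measurable cost. Slice
sampling is tuning-free, and the scheme is exactly reproducible given the
seed — two fits with the same configuration are bit-identical. Priors are
weakly informative: zero-centered normals with SD 2 for population means
and regression coefficients, half-normal(1) for population SDs and for
the positive criteria/threshold increments (ordering is enforced by
construction, not rejection). Excluded parameters in pruned model
variants are fixed at zero. Convergence is monitored with split-R̂ and
effective sample sizes on the population-level parameters; fits with
max R̂ above 1.05 carry `converged = FALSE` and are excluded (and counted)
in recovery loops. A probability floor of 1e−300 on observed categories
makes pathological parameter regions fail loudly in diagnostics rather
than crash.

The `"reference"` budget is the full protocol (5 chains × 5000
iterations, half warmup). The default `"test"` budget (2 × 900) and
the replicate-study budgets below are the package's scaled-down settings
chosen so that the simulation studies stay desk-scale: parameter recovery
uses 8 replicates of 30 subjects × 120 trials (2 chains × 1200), model
recovery 10 replicates of 12 subjects with single 600-iteration chains
per variant, and SDT calibration 20 replicates of 10 subjects × 120
trials. At these sizes the Monte-Carlo error of the reported summaries is
small relative to the thresholds they are compared against.

# Model comparison and evidence

The three main parameters (`δp`, `δs`, `γ`) give eight variants (`τ` and
the criteria are always included). Variants are ranked by LOOIC
(−2 × elpd), computed by Pareto-smoothed importance sampling from the
pointwise log-likelihood matrix: per observation, the upper tail of the
importance ratios is replaced by expected order statistics of a
generalized Pareto distribution fitted with the Zhang–Stephens
profile-posterior method, weights are truncated at the raw maximum, and
observations with tail-shape k̂ > 0.7 (or degenerate tails, which fall
back to truncated raw weights) are counted and reported. Directional
hypotheses are summarized with evidence ratios — the ratio of posterior
draws in the hypothesized direction to those against, capped at the
number of draws when unanimous; 1–3.2 is conventionally weak, 3.2–20
substantial, above 20 strong evidence.

# Ordinal signal-detection analyses

The ordered-probit regression treats the 11-point judgment as an ordinal
response on a unit-noise latent axis with ten free, strictly increasing
thresholds (first threshold free, positive increments — unlike the
accumulation model they are not forced symmetric). The stimulus is coded
`s = col/2 = ±0.5`, so the coefficient of `s` *is* the discrimination
ability d′ (the latent separation between the two stimulus classes), and
condition effects — the five-level factor absent/early-correct/
late-correct/early-wrong/late-wrong, difficulty, and z-scored trial
number — enter only in interaction with `s`, i.e. as Δd′. Main effects of
condition (criterion shifts) are deliberately omitted from the default
model, matching the d′-focused question; subject identity enters as a
random intercept on the latent scale. The accompanying binary probit
models regress correctness (50% judgments dropped) on social-information
validity or presence plus difficulty, color, and trial number.

The contrast table reports each Δd′ against zero, early−late within
correct and within wrong social information, |correct|−|wrong| within
each timing, and the timing-symmetry contrast, each with its evidence
ratio. Under a drift-free (shift-only) generator the early−late contrasts
are centered on zero; under the default truth they are positive for
correct and negative for wrong social information — the ordinal analysis
recovers the accumulation model's timing signature.

# Numerical and design choices

* Criteria/threshold ordering by construction (cumulative positive
  increments); no rejection steps.
* The undecided category `j = 6` has `correct = NA`; it scores 0 points
  and is dropped from accuracy analyses.
* The exclusion fixture used in tests sets the latency mean to 0.9 s
  ("attentive" subjects): at the study's own latency level, honest
  subjects occasionally exceed 10 late responses, which is a property of
  the rule, not a bookkeeping error; the fixture isolates the
  bookkeeping.
* Monte-Carlo agreement checks compare binned frequencies to analytic
  probabilities within 3 binomial SEs; across the 550 category
  comparisons of the randomized oracle suite, the expected extreme of
  |z| is above 3, so the suite requires 99.5% of comparisons within 3 SE
  and caps the maximum at 4.5.
* Which parameters vary by subject is a genuinely open design choice
  here; the package makes all five accumulator parameters
  subject-level with shared criteria, the minimal structure that
  "controls for subject-level differences". The priors above are likewise
  the package's own choices and are overridable in `sampler_config()`.
* No-social trials enter the accumulation likelihood with social terms
  zeroed; filler trials never enter any analysis.

# Known limitations

The sampler is a single-site scheme: for strongly correlated posteriors
(e.g. `γ` with `δs`) its effective sample size per iteration is modest,
which the ESS diagnostics make visible. LOOIC differences between nested
variants that differ only in the weak social drift are small relative to
their SE at desk scale, exactly as in the original analysis, where model
selection was nevertheless stable. The generator's latency law is
calibrated only to the reported mean social-information-to-judgment
times; no claim is made about latency distributions. Empirical
coefficients from the human experiments are not reproduced: the package
ships no behavioral data, and all quantitative guarantees concern
synthetic data from its own generator.
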