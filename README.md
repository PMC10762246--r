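# socialdrift

Does social information sway a perceptual judgment more when it arrives
early? `socialdrift` is an R package for analyzing — and simulating — a
two-alternative color-discrimination task in which another person's choice
appears either early or late in a deliberation phase before an 11-point
confidence judgment. It is written for cognitive modellers who want a
complete, reproducible pipeline: trial-schedule construction, a generative
simulator, preprocessing with incentive-compatible scoring and exclusion
rules, hierarchical Bayesian evidence-accumulation modelling, model
comparison, and ordinal signal-detection analyses.

## The model

The latent evidence at the moment of judgment is normal with

```
E(L) = τ·col + δp·DT + (δs·ST + γ)·λ,    var(L) = σ·DT,  σ = 1
```

where `DT` is the time from stimulus onset to judgment, `ST` the time from
social-information onset to judgment, `col` the dominant color (±1), `λ`
the validity of the social information (±1), `δp` the personal drift
(`δ_easy`/`δ_hard`), `δs` the **social drift** (continuous integration),
`γ` the **social shift** (instantaneous update), and `τ` a color bias.
Ten mirror-symmetric criteria cut the evidence axis into the 11 confidence
categories, giving cumulative-normal category probabilities. A pure shift
predicts no effect of social-information timing; a drift makes the
early−late difference in mean evidence exactly `δs·ΔST`. Model variants
with every combination of `δp`, `δs`, `γ` (eight in all) are fitted
hierarchically (slice-within-Gibbs MCMC in C++) and compared by PSIS-LOO
(LOOIC). An ordered-probit regression with stimulus coded ±0.5 expresses
the same data as discrimination ability d′ with per-condition Δd′ and
evidence ratios for directional hypotheses.

## A worked example

```r
library(socialdrift)

# simulate a 12-subject experiment at the default (Experiment-1-like) truth
pop <- population_spec(n_subjects = 12)
sim <- simulate_experiment(pop, design_config(seed = 1), seed = 2)

# preprocess: subject exclusions, then the accumulation-trial filter
excl <- apply_subject_exclusions(sim$data)
fit_data <- apply_trial_filters(excl$data, "accumulation")

# fit the full shift+drift model and summarize
fit <- fit_accumulator(fit_data, "full", sampler_config(), seed = 3)
print(tidy(fit), n = 6)
#> # A tibble: 20 x 7
#>   term          estimate std.error conf.low conf.high   rhat   ess
#>   <chr>            <dbl>     <dbl>    <dbl>     <dbl>  <dbl> <dbl>
#> 1 mu_delta_easy   0.984     0.118    0.746      1.21   0.999  887.
#> 2 mu_delta_hard   0.560     0.137    0.288      0.838  1.000 1156.
#> 3 mu_delta_s      0.0708    0.0771  -0.0689     0.215  1.01   220.
#> 4 mu_gamma        2.42      0.378    1.66       3.16   1.00   313.
#> 5 mu_tau         -0.0685    0.167   -0.403      0.257  1.01   649.
#> 6 sd_delta_easy   0.355     0.0917   0.226      0.584 NA       NA
#> # i 14 more rows

compute_looic(fit)
#> # A tibble: 1 x 5
#>   looic    se   elpd p_loo n_high_k
#>   3249.  52.4 -1624.  50.8        0
```

The population means used to generate these data were `δ_easy = 0.90`,
`δs = 0.18`, `γ = 2.41`: the posterior recovers the strong personal drift
and the large instantaneous shift, while the weak social drift is
estimated with appropriately wide uncertainty at this sample size.
`compare_variants()` fits all eight variants and ranks them by LOOIC;
`parameter_recovery()` runs simulate-and-refit studies;
`build_sdt_design()` + `fit_ordered_probit()` + `dprime_contrasts()`
produce the d′ analysis; `run_pipeline(pipeline_config(...))` chains every
stage and writes a report bundle.

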