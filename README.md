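# gambleb

Prospect-theory modelling of risky choice on mixed gambles, with
hierarchical empirical-Bayes parameter estimation and Bayesian model
comparison.

## What this is for

In the mixed-gambles paradigm a participant sees 169 gambles — every
combination of a gain in {€6, €8, …, €30} and a loss in {€3, €4, …, €15} —
and accepts or rejects each 50/50 lottery. Choice patterns on this task
decompose risky choice into interpretable components, which is what makes
it useful in computational psychiatry: for example, testing whether
dopaminergic medication in Parkinson's disease increases gambling because
patients weigh losses less (loss aversion) or because they gamble more
regardless of value (a gambling bias), and whether those drug effects track
depression severity.

The model: each gamble's subjective utility is

    SUG = 0.5 · Gain − 0.5 · Loss · λ

with loss aversion λ ≥ 0 (λ > 1 means losses loom larger than gains), and
acceptance follows a biased softmax

    p(accept) = 1 / (1 + exp(−(μ·SUG + c)))

with inverse temperature μ (choice consistency) and a value-independent
gambling bias c (c > 0: accept regardless of value). Per-subject-per-session
parameters are estimated under a shared group-level normal prior whose mean
and variance are themselves estimated by an iterative empirical-Bayes
(EM) procedure with Laplace posterior approximations. The full model
(λ, μ, c) is compared against a reduced model (c ≡ 0) by negative
log-model evidence (NLME; lower is better).

Since no participant data are distributed with this package, a synthetic
cohort generator reproduces the study design (23 controls tested once, 22
nondepressed and 21 depression-history patients tested ON and OFF
medication) with group-typical parameters, depression scores and built-in
drug effects, so the entire analysis chain is testable end to end.

## Worked example

```r
library(gambleb)

# one subject: 169-gamble schedule, simulated choices, ML fit
sched   <- build_schedule(seed = 1)
choices <- simulate_choices(sched, lambda = 1.5, mu = 1, c_bias = -1, seed = 2)
mean(choices$accepted)
#> [1] 0.58
fit <- fit_map_individual(choices, flat_prior("full"), "full", seed = 3)
round(fit$theta, 3)
#> lambda     mu      c
#>  1.451  1.028 -1.434

# twenty such subjects under the hierarchical model
pool <- dplyr::bind_rows(lapply(1:20, function(i)
  simulate_choices(build_schedule(i), lambda = 1.5, mu = 1, c_bias = -1,
                   seed = 100 + i, subject_id = sprintf("S%02d", i))))
hf <- fit_hierarchical(pool, "full", seed = 4)
round(hf$prior$mean, 3)
#> lambda     mu      c
#>  1.478  1.038 -1.150

# is the gambling bias worth its extra parameter?
hr <- fit_hierarchical(pool, "no_bias", seed = 4)
compute_nlme(hf)$nlme; compute_nlme(hr)$nlme
#> [1] 781.7
#> [1] 796.8
select_model(compute_nlme(hf), compute_nlme(hr))
#> [1] "full"
```

The single-subject MAP lands near the generating (1.5, 1, −1); pooling 20
subjects tightens the group means, and the model comparison correctly
prefers the full model because the generating bias c = −1 is nonzero.

## The analysis workflow

Numbered drivers under `analysis/` run the full study-like analysis on a
synthetic cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R     # cohort CSVs (choices, clinical, truth)
Rscript analysis/02_screen_subjects.R     # utility-maximizer screen
Rscript analysis/03_fit_and_compare.R     # hierarchical fits, NLME comparison
Rscript analysis/04_behavioral_metrics.R  # acceptance rates, loss-sensitivity curves
Rscript analysis/05_group_statistics.R    # drug-effect and correlation statistics
```

On the default cohort (seed 20260920) the fits converge in a few EM
iterations per variant; the full model beats the reduced model (NLME
3704.0 vs 3925.8 over 86 patient subject-sessions), the nondepressed
group's median gambling bias rises from −2.43 OFF to −1.42 ON
(Wilcoxon V = 223, p = 0.0009) while its median loss aversion barely moves,
and across the 43 patients the drug effect on λ correlates negatively with
OFF-state depression scores (Spearman ρ = −0.33, p = 0.032) — the
qualitative pattern the generator builds in, recovered from raw simulated
choices. `run_pipeline()` performs the same chain as a single deterministic
function call.

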