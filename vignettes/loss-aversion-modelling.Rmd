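---
title: "Modelling loss aversion and gambling bias in mixed-gamble choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling loss aversion and gambling bias in mixed-gamble choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the scientific question

`gambleb` analyses accept/reject decisions on *mixed gambles*: 50/50
lotteries offering a potential gain and a potential loss. The task design it
targets is a 13 × 13 factorial grid — gains €6 to €30 in €2 steps, losses €3
to €15 in €1 steps — in which every gain–loss pair is presented exactly once
in randomized order (169 trials per session, split 57/56/56 into three
runs). The asymmetric ranges reflect the empirical regularity that people
weigh losses roughly twice as heavily as gains, and keep typical behaviour
away from all-accept and all-reject ceilings. Gambles are not resolved
during the session, so there is nothing to learn trial-to-trial and trials
can be modelled as exchangeable.

The motivating application is dopaminergic medication in Parkinson's
disease: patients perform the task twice, once ON and once OFF their
medication, and the question is *which computational component of risky
choice the drug moves* — the relative weighting of losses, or a
value-independent propensity to gamble — and whether that drug effect
covaries with depression severity.

## The choice model

The subjective utility of a gamble follows prospect theory with a linear
value function and unweighted probabilities:

$$SUG = p_{gain}\,Gain - p_{loss}\,Loss\,\lambda, \qquad
p_{gain}=p_{loss}=0.5,$$

where $Loss$ is the absolute loss magnitude and $\lambda \ge 0$ is loss
aversion ($\lambda>1$: losses loom larger; $\lambda=1$: gain–loss neutral).
Linearity and unweighted 0.5 probabilities are deliberate simplifications:
over this narrow stake range a curvilinear value function and probability
weighting are not identifiable and add nothing but variance.

Acceptance is a biased logistic (softmax) rule:

$$p(\text{accept}) = \frac{1}{1 + e^{-(\mu\,SUG + c)}}$$

with inverse temperature $\mu$ (1/€; higher = more value-driven choice) and
gambling bias $c$ (log-odds units; $c>0$ pushes toward accepting gambles
regardless of their value). The sign convention places $c$ *additively on
the logit*, so that positive $c$ raises acceptance — the defining property
of a gambling propensity. In the hierarchical fit parameters are
box-constrained to $\lambda,\mu \in [0,10]$ and $c \in [-10,10]$;
probabilities are clamped to $[10^{-12}, 1-10^{-12}]$ before logs so
saturated parameter regions stay finite.

A *reduced* variant forces $c \equiv 0$ (no value-independent bias) and is
fitted as its own hierarchical model — not by zeroing $c$ after the fact —
so that model comparison genuinely trades fit against one fewer free
parameter per subject.

## Hierarchical empirical-Bayes estimation

Every subject–session is one unit $n$ with parameters $\theta^n$. All units
in a fitting pool share a diagonal normal prior
$N(\theta \mid \Theta, \Sigma)$ whose moments are estimated from the data:

1. **E-step.** For each unit, maximize
   $\log P(D^n \mid \theta) + \log N(\theta \mid \Theta, \Sigma)$ by
   box-constrained L-BFGS-B with analytic gradients, from multiple seeded
   starts (prior mean, warm start from the previous iteration, random draws
   from the prior). The Hessian $H_n$ of the negative log-posterior at the
   MAP — computed analytically and verified against central finite
   differences in the tests — defines the Laplace approximation of the
   unit's posterior.
2. **M-step.** Update
   $\Theta' = \tfrac1N\sum_n \theta^n$ and
   $\Sigma' = \tfrac1N\sum_n \left(\theta^{n2} + \mathrm{diag}(H_n^{-1})\right) - \Theta'^2$,
   the standard EM moment update for a random-effects normal with Laplace
   posteriors, floored elementwise at $10^{-3}$.
3. Iterate until the largest absolute change in $\Theta$ and $\Sigma$ drops
   below `tol` ($10^{-4}$ by default, `max_iter = 500`).

Treating each subject–session (rather than each subject) as a unit lets ON
and OFF parameters differ freely while every unit is regularized toward the
same group distribution — so ON/OFF differences in the estimates cannot be
an artifact of session-specific priors. Two pooling strategies mirror the
two passes a drug study needs: patients only (both groups, both sessions,
one prior) for within-patient drug effects, and controls-plus-patients per
session for patient–control comparisons.

Initialization uses per-unit unpenalized ML fits with group moments from
their 5%-trimmed mean and variance; the trimming keeps a single wild ML
estimate (e.g. a near-saturated subject) from inflating the starting prior.
MAP estimates within $10^{-3}$ of a box bound are flagged `at_boundary`
(and reported by `screen_boundary()`): the Laplace approximation is
unreliable there, and in practice only contaminant-like units hit bounds.
The analytic Hessian remains exact at a bound and is used as-is; a
finite-difference fallback (and a pseudo-inverse for numerically singular
Hessians) protects the moment update.

## Model evidence

Model comparison uses the negative log-model evidence

$$NLME \approx -\sum_n \log P(D^n\mid\theta^n)
 - \sum_n \log N(\theta^n \mid \Theta, \Sigma)
 - \tfrac12 m N \log 2\pi
 + \tfrac12 \sum_n \log |H_n|
 + m \log N,$$

with $m$ free parameters per unit (3 full, 2 reduced) and $N$ units:
individual parameters are marginalized by Laplace approximation and the
$2m$ group parameters by a Bayesian-information penalty. Lower is better;
an exact tie goes to the reduced model on parsimony. Per-unit terms are
retained in the returned object so every evidence value can be audited
term by term.

## Behavioural screening

The screen asks whether a subject–session behaves like a utility maximizer
(acceptance rising with gains, falling with losses). Two failure modes are
flagged:

- **Inverted** responders (sign-flipped utility): the unpenalized ML fit
  with $\mu$ free in $[-10,10]$ lands at $\mu < 0$ *and* the acceptance
  trend in gain is negative.
- **Random** responders: acceptance rate in $[0.35, 0.65]$ and a
  likelihood-ratio test (df = 3) of the gain/loss logistic model against
  the coin-flip null that fails to reject at $\alpha = 0.01$.

The randomness rule is deliberately an LRT rather than a threshold on the
fitted $\mu$ itself: on 169 trials the ML $\mu$ of a true coin-flipper has
a sampling SD of about $0.04$ (from the logistic information
$SE(0.5\mu) \approx 1/\sqrt{0.25 \cdot 169 \cdot \mathrm{var}(gain)}$), so
any small-$|\mu|$ cutoff either misses a large fraction of coin-flippers or
starts catching genuine low-temperature subjects. Value-driven subjects sit
astronomically far from the coin-flip null ($z \approx 24\mu$ on the gain
coefficient), so the strict $\alpha$ costs essentially nothing in false
exclusions; the randomness check runs before the inverted check because a
coin-flipper's noise-level trends carry arbitrary signs. All-accept and
all-reject sessions are retained with a warning since trends are undefined
there. In the test suite this screen excludes ≥ 99/100 random and 100/100
strongly inverted contaminants while retaining 100/100 well-behaved
simulated subjects.

## Model-free measures

`proportion_accepted()` gives the compound risky-choice measure per
stratum. `loss_sensitivity_curve()` summarizes raw loss sensitivity: for
each loss magnitude, gains are pooled and the log ratio
$\log\frac{R+0.5}{A+0.5}$ of rejected to accepted counts is computed
(Haldane–Anscombe correction for empty cells), the loss axis is centred on
the mid-level of the observed range ("relative loss"), and a least-squares
slope across the 13 levels summarizes the curve — steeper means more loss
sensitive. Pooling within loss level (rather than differencing pairs of
trials) is this package's reading of "averaging out" gain effects; it keeps
the x-axis in euros and the counts exact.

## The synthetic cohort generator

No patient data ship with the package; `generate_cohort()` produces
cohorts with the statistical structure the analysis assumes, so every
downstream stage is testable end-to-end:

- **Design**: 23 controls tested once; 22 nondepressed and 21
  depression-history patients tested ON and OFF; a fresh randomized
  169-trial schedule per subject–session; session order counterbalanced
  and recorded.
- **Parameters**: OFF-session $(\lambda, \mu, c)$ from truncated normals
  inside the model box, centred per group at the observed per-group
  medians of the fitted parameters ($\lambda$: 1.37/1.01/1.51, $\mu$:
  1.06/0.89/0.93, $c$: −0.65/−2.71/−1.73 for HC/nondepressed/depressed);
  spreads (0.6/0.4/1.5) are conservative choices since subject-level
  dispersions are not published.
- **Drug effects**: the nondepressed group's $c$ shifts by +1.66 ON (the
  OFF-to-ON difference of the published medians), the depression-history
  group's by +0.43; the per-subject drug effect on $\lambda$ is
  $-0.05 \cdot (BDI_{OFF} - \overline{BDI}_{group})$ plus $N(0, 0.25^2)$
  noise, which makes higher OFF-state depression couple with larger
  drug-induced drops in loss aversion and — after estimation noise — puts
  the cohort-level Spearman correlation near the observed −0.35.
- **Covariates**: BDI from the published group means/SDs (9.9 ± 6.1,
  4.0 ± 2.3, 3.1 ± 2.1), rounded and truncated at 0; levodopa-equivalent
  dose and impulse-control-disorder flags at their published group
  frequencies.

What the generator does *not* emulate, and hence what passing tests cannot
show: response times and the 4 s deadline; any coupling between the drug
effect on *BDI itself* and the drug effect on $\lambda$ (the generator's
BDI change is noise around a group shift, so the $\Delta BDI$–$\Delta\lambda$
correlation is near zero even though the $BDI_{OFF}$–$\Delta\lambda$
correlation is built in); order effects; medication dose–response; and any
non-normality or covariance structure of real subject-level parameters.
Real data can also violate the model class itself (e.g. probability
weighting), which no synthetic-recovery result speaks to.

## Numerical choices

- Bounds $[0,10]^2 \times [-10,10]$ in native space; the prior is evaluated
  in native space with box-constrained optimization, with no transform to
  unbounded space — matching how interior-point MAP fitting is typically
  done for this model and keeping the prior moments interpretable in
  parameter units.
- Multi-start MAP (≥ 5 starts; warm starts inside EM) guards against the
  rare multimodality induced by the $\mu\lambda$ product; in testing, the
  optimum never fell below an exhaustive 0.05-lattice search over the box.
- On that lattice comparison: the likelihood ridge couples $c$ to
  $\mu\lambda$, so the lattice's half-step discretization of $\lambda$
  displaces the conditionally optimal $c$ by up to
  $\mu \cdot \overline{loss}/2 \cdot 0.025 \approx 0.2$. The oracle test
  therefore compares $\lambda$ and $\mu$ coordinate-wise, compares $c$
  through its conditional optimum at the lattice $(\lambda,\mu)$, and
  requires the optimizer never to be beaten in likelihood.
- Variance floor $10^{-3}$ on $\Sigma$ keeps the E-step well-posed when a
  parameter's population spread collapses; `tol = 10^{-4}`,
  `max_iter = 500` for the EM loop.
- Bootstrap SEs of medians use $10^5$ resamples (seeded) by default.
- Statistical branches follow common package defaults: exact signed-rank /
  Mann–Whitney enumeration at small untied samples, continuity-corrected
  normal approximations with tie corrections otherwise; Pearson and
  Spearman p-values via the $t$-approximation with $n-2$ df (which
  reproduces published correlation p-values at these sample sizes);
  Shapiro–Wilk at $\alpha = 0.05$ for normality routing; no
  multiple-comparison correction (flagged in reports rather than applied).
- Table summaries report the median, the range as max − min (a single
  number), and the bootstrap SE of the median.

## Problem sizes in the test suite

The suite exercises parameter recovery with 40 subjects × 169 trials over
10 seeds (group means recovered within 0.15 for $\lambda,\mu$ and 0.35 for
$c$ on average; true-vs-recovered per-subject $\lambda$ correlation
≈ 0.95), model recovery with 20-subject cohorts over 10 seeds per
condition, the lattice-oracle comparison with 20 subjects, and screening
over 100 seeds per contaminant type. These sizes were chosen to estimate
each property with comfortable margins while keeping the default test run
quick enough to be part of routine development.

## Known limitations

- Diagonal $\Sigma$: parameter covariances (e.g. the empirical
  $\lambda$–$c$ coupling) are not modelled in the prior.
- Laplace evidence is a second-order approximation; it is exercised here
  for nested comparisons with large NLME margins, where its ranking is
  stable, not for finely balanced non-nested comparisons.
- Units at box bounds contribute approximate Laplace terms; they are
  flagged, and in realistic cohorts they are the subjects the screen
  removes anyway.
- The mixed ANOVA assumes complete two-session cases and two groups; it
  deliberately implements the classic split-plot decomposition rather than
  a general mixed model (`lme4` would be the tool once designs grow
  unbalanced factors).
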