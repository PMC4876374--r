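---
title: "Models and methods behind cardiometa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cardiometa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiometa)
```

cardiometa analyses forced-choice own-heart-sound recognition data: 30
trials per subject (15 own-heart, 15 other-heart samples), a binary
self/other response per trial, a continuous 0–100 confidence rating, and
an accompanying heartbeat-counting task. This vignette documents the
statistical models, the parameters that matter, the numerical choices, and
what the synthetic-data generator does and does not emulate.

## The binomial chance model

Under the null that a subject cannot discriminate, each trial is an
independent Bernoulli(½) guess. The classification rule is built on the
*exact point probability*: the above-chance bound `k_upper` is the
smallest k above n·p₀ with C(n,k)p₀ᵏ(1−p₀)ⁿ⁻ᵏ ≤ α, and at p₀ = ½ the
below-chance bound is its mirror n − k_upper. With n = 30 and α = .05
this yields k_upper = 20 (point probability 0.028) and k_lower = 10, i.e.
accuracy bands of roughly ⅔ and ⅓.

Two deliberate choices here:

* **Point probability, not tail.** The criterion could equally have been
  defined through the upper-tail probability P(X ≥ k); at n = 30 both
  rules give k_upper = 20, but the p-value attached to the criterion
  differs (0.028 vs 0.049). We use the point-probability rule throughout
  and apply it consistently at every n — e.g. at n = 10 it gives
  k_upper = 8 (C(10,8)/2¹⁰ = 0.044), where the tail rule would give 9.
* **Trial counts, not rounded accuracy bands.** Group bounds are defined
  on integer trial counts; displayed accuracy bands (0.33/0.67) are
  rounded summaries of those counts, never the operative rule (20/30 =
  0.667 would fail a literal "above 0.67" reading).

Group distributions are tested with the Pearson goodness-of-fit χ²
against equal expected counts and summarized by Cohen's ω = √(χ²/N),
omnibus over the three groups and pairwise 2-cell post hocs without
multiplicity adjustment. The implementation keeps the identity
ω²·N = χ² to machine precision, which the tests verify against an
exact-rational oracle (k·ΣO² − N²)/N.

## Heartbeat-counting accuracy

The Schandry tracking index is the unweighted mean over intervals of
1 − |recorded − counted|/recorded. Intervals are weighted equally rather
than by duration — the convention of the heartbeat-tracking literature —
and an interval in which the subject reports more than twice the recorded
beats contributes a *negative* term: clamping it to zero would silently
alter data, so the value is kept and a warning raised. `recorded ≥ 1` is
enforced at I/O time because the index divides by it.

## Type-1 SDT

With "signal" = own-heart stimulus and hit = responding SELF to it,
d′ = z(HR) − z(FAR) and c = −(z(HR)+z(FAR))/2. Rates are kept inside
(0, 1) by the log-linear correction (add 0.5 to each of the four type-1
cells) by default; the half-count rule (replace 0 with 1/(2N), 1 with
1 − 1/(2N)) and raw rates are selectable. The log-linear default is
symmetric and defined for every input, at the cost of a slight shrinkage
of extreme d′.

A structural caveat of balanced designs: a subject with exactly half the
trials correct necessarily has equal hit and false-alarm *counts*, so
d′ = 0 after any symmetric correction, and the relative criterion
c′ = c/d′ — and with it meta-d′ — is undefined. The pipeline reports such
subjects with `NA` meta-d′ and a logged note rather than failing, and the
cohort inference uses complete cases.

## Confidence binning and the type-2 model

The confidence scale is a continuous VAS, so the type-2 model first needs
discrete rating levels. We bin at the subject's own empirical j/K
quantiles (K = 4 by default, configurable): within-subject quantiles
protect against idiosyncratic use of the scale (a subject who never rates
above 60 still contributes all K levels), and a value falling exactly on
a cut point goes to the lower level, deterministically. Binning errors
out — advising a smaller K — when fewer than K distinct values exist or
quantiles tie.

Counts are cross-tabulated by response side × stimulus truth × level. A
response side containing any empty cell gets 1/(2K) added to each of its
cells, keeping its observed cumulative rates strictly inside (0, 1) with
minimal distortion; the untouched side is not padded.

## meta-d′ by sum-squared-error fitting

The model observer is an equal-variance Gaussian with sensitivity
`meta_d` (stimulus means ±meta_d/2, unit variance) whose type-1 criterion
is *locked* to meta_c = c′·meta_d, the subject's relative criterion
scaled to the meta level — the convention that makes meta-d′ directly
comparable to d′. For the SAYS_SELF side with type-2 criterion
q ≥ meta_c,

P(conf ≥ level | stimulus s, SAYS_SELF) = [1 − Φ(q − μ_s)] / [1 − Φ(meta_c − μ_s)],

and the SAYS_OTHER side uses the mirrored lower-tail ratio with criteria
below meta_c. The fit minimizes the sum of squared differences between
observed and model cumulative type-2 probabilities — type-2 HR and FAR at
each of the K − 1 levels, both response sides, 4(K−1) terms — jointly over
meta_d and the 2(K−1) criteria.

Numerical choices:

* criteria are parameterized as meta_c ± cumsum(exp(·)), which enforces
  the required ordering by construction instead of by constraint;
* meta_d is restricted to [−5, 5] via a quadratic penalty (beyond ±5 the
  normal tails underflow and the objective flattens);
* the objective is smooth but ridge-prone, so a derivative-free
  Nelder–Mead search is run from 8 restarts (1 deterministic start at the
  type-1 d′ plus 7 seeded random starts), keeping the best; a fit is
  declared converged when the optimizer reports convergence or the SSE
  falls below 10⁻⁶;
* conditional-probability denominators are floored at 10⁻¹² to avoid
  0/0 at extreme criteria.

Self-consistency holds by construction: counts generated from the model
itself are recovered with SSE ≈ 0, which the test suite checks, along
with large-sample parameter recovery, robustness to type-1 criterion
shifts, and dominance of the returned optimum over random feasible
parameter draws.

## Inference layer

meta-d′ vs d′ is a classical paired t (df = n − 1) with Cohen's d = mean
difference / SD of differences. Correlations with counting accuracy
default to Pearson (switchable to Spearman). The comparison of the two
dependent correlations sharing the counting-accuracy variable uses
Williams' t — the statistic Steiger (1980) recommends and the computation
behind the widely used dependent-correlation calculators — with
df = n − 3 and a positive-semi-definiteness check on the correlation
triple. Group comparisons use Kruskal–Wallis with tie correction; a
pooled sample with all values identical returns H = 0, p = 1 rather than
0/0. No multiple-comparison correction is applied anywhere, matching the
analysis the pipeline reproduces.

## The synthetic observer

`simulate_subject()` draws a balanced stimulus sequence in random order;
per trial the decision variable is x ~ N(±d′/2, 1), the response is
SAYS_SELF iff x > c, type-2 evidence is x₂ = x + N(0, σ_meta), and
confidence is a fixed monotone squashing of |x₂ − c| onto [0, 100]
(100·(2Φ(·) − 1) by default). Additive Gaussian type-2 noise is one of
several published conventions for metacognitive inefficiency; it was
chosen because it has a single interpretable knob whose σ_meta = 0 limit
provably yields meta-d′ = d′, giving the test suite a sharp oracle.
Note that the degradation is *steeper* than the naive 1/√(1+σ²) scaling,
because noise that carries x₂ across the criterion produces confidently
wrong ratings.

Defaults describe the studied cohort: 27 subjects, 30 trials, d′ = 0.8
with between-subject SD 0.23, neutral criterion, counting accuracy
mean 0.75 / SD 0.21, and a 0.4 coupling between metacognitive efficiency
and counting accuracy. σ_meta defaults to 1.0, calibrated on 20,000-trial
simulations so the large-sample meta-d′ at d′ = 0.8 is ≈ 0.3, the
condition the cohort-level analysis expects. `simulate_cohort()` scatters
d′ and c normally, σ_meta log-normally, and couples counting accuracy
(Beta-distributed) to metacognitive efficiency through a Gaussian copula,
returning the latent truth table for recovery tests. Counting records use
counted = round(recorded·(1 − e)) with a per-subject error rate e, which
keeps the index in [0, 1] by construction (rounding means small error
rates can land exactly at 1).

What the generator does **not** emulate: serial dependence between trials
(fatigue, criterion drift), lapses and missed responses, heart-rate
differences between stimuli, and any audio-level structure. Passing tests
therefore validate the *estimators* under the stated generative
assumptions, not the auditory task itself.

## Problem sizes and determinism

The test suite exercises the estimators at sizes chosen to make sampling
noise negligible relative to the asserted tolerances: 10,000-trial
observers for meta-d′ recovery (±0.1) and bias robustness (±0.15),
2,000 replicates for the dependent-correlation null rejection rate
(5% ± 2 pp), 3,000 subjects for copula-coupling checks, and a scaled-down
60-subject × 400-trial cohort for directional efficiency–accuracy
recovery (the full-scale version would add hundreds of meta-d′ fits for
no extra information). All simulation flows through explicit seeds with
R's default RNG, and the pipeline seeds each subject's optimizer restarts
from a hash of the subject id, so removing one subject can never perturb
another's estimates and re-runs are byte-identical.

## Known limitations

* meta-d′ from 30 trials is a noisy estimate however it is fitted; the
  SSE approach reports the fit SSE and convergence flag per subject, but
  cohort-level conclusions should rest on the paired contrast, not on
  individual values.
* The SSE objective weights all cumulative rates equally regardless of
  the trial counts behind them; maximum-likelihood and hierarchical
  Bayesian variants are deliberately out of scope.
* Only equal-variance SDT is implemented; unequal-variance observers will
  bias both d′ and meta-d′.
* The binomial classification assumes exchangeable trials; serial
  dependence would make the effective test size smaller than nominal.
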