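---
title: "Choosing mastery criteria with beta-binomial inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing mastery criteria with beta-binomial inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miebl)
```

## The model

A discrete-trial assessment of one skill component is modelled as `n`
exchangeable Bernoulli trials with latent success probability `p`, the
student's true mastery level. The practitioner observes `x` correct
responses and wants to know how much confidence the event "criterion met"
confers about `p`. With a Beta(`a0`, `b0`) prior on `p`, conjugacy gives

$$p \mid x, n \sim \mathrm{Beta}(x + a_0,\; n - x + b_0),$$

from which the package computes three scalar summaries:

* `mastery_prob()` — the tail probability
  $b = \Pr(p \ge p^* \mid x, n)$, the confidence that true mastery meets
  the desired level $p^*$;
* `lower_credible_bound()` — the posterior $a$-quantile $q$, so that
  $\Pr(p \ge q) = 1 - a$;
* `mean()` — the posterior mean $(x + a_0)/(n + a_0 + b_0)$, the expected
  true mastery of students observed at exactly `x` of `n`.

Conditioning is on the exact observed count `x`, not on the event
$x/n \ge \tau$: criterion tables index rows by the number correct, and a
report describes the student actually observed. A mixture over all counts
at or above the criterion is available empirically in the simulation
module (`conditioning = "at_least"`) but is deliberately not part of the
inferential core.

### Why the Jeffreys prior

The default prior is Jeffreys' Beta(½, ½), the reference prior for a
binomial proportion. It is invariant to reparameterisation, proper at the
degenerate counts `x = 0` and `x = n` (both common in DTT, where 100%
criteria are routine), and less informative at the endpoints than the
uniform Beta(1, 1), which pulls tail probabilities for perfect scores
noticeably toward ½ — under the uniform prior, 5 of 5 correct yields
`Pr(p ≥ 0.9) ≈ 0.47` instead of `0.71`. The prior is a parameter of every
entry point (`mastery_prior()`), so uniform or custom Beta shapes can be
substituted to probe sensitivity.

## Assumptions and their limits

* **Independence among trials.** The binomial likelihood presumes each
  trial's outcome does not influence the next; in practice this is
  supported by an adequate inter-trial interval. Serially dependent
  responding (momentum, fatigue, prompting carry-over) is outside the
  model; criteria based on consecutive correct responses or
  first-opportunity responding correspond to different likelihoods and are
  not implemented.
* **Exchangeable items.** All items probing the skill component are
  treated as equally difficult for the student; `p` is a property of the
  (student, component) pair, not of individual items.
* **No drift within assessment.** `p` is constant across the `n` trials;
  learning during assessment would bias the posterior toward earlier,
  weaker performance.

## Tunable parameters

| parameter | meaning | default | note |
|---|---|---|---|
| `p_star` | desired true-mastery threshold (proportion) | 0.90 | the level the practitioner wants assurance about |
| `a` | tail level of the credible bound | 0.05 | 0.05 gives a "95% chance" statement |
| `prior` | Beta shapes on `p` | Jeffreys (½, ½) | see above |
| `mc` | performance criterion (integer percent) | — | must make `mc/100 · n` integral |
| `reps` | Monte Carlo replicates | 200000 | SE of a fraction ≈ 0.001 at the default |
| `max_n` | planner search bound | 10000 | a practical ceiling for DTT trial counts |

## Numerical choices

* Tail probabilities and quantiles delegate to `pbeta()`/`qbeta()`, i.e.
  the regularized incomplete beta function and its inverse; the test suite
  cross-checks both against an independent trapezoid-quadrature oracle
  (endpoint regions integrated analytically by series, so posteriors with
  a singular endpoint are covered) to below `1e-6` over all `n ≤ 20`.
* `p_star = 1` returns `b = 0`: the continuous posterior puts no mass on
  the point {1}. Symmetrically `p_star = 0` returns 1. `n = 0` is
  rejected rather than returning the prior, so a report can never present
  prior-only "mastery" as evidence.
* Density grids (`density()` on a posterior, report overlays) are evenly
  spaced on [0, 1] with evaluation clipped to `[1e-9, 1 - 1e-9]`. When
  both posterior shapes are ≥ 1 the trapezoid integral of the default
  4097-point grid is 1 within `1e-3`. When a shape is below 1 (`x = 0` or
  `x = n`) the density is unbounded at an endpoint and the clipped grid is
  a plotting surface only — its trapezoid integral is dominated by the
  clipped endpoint value and is **not** a normalisation check; quadrature
  against such posteriors should use the distribution functions instead.
* Display rounding is frozen to the reporting conventions: probabilities
  at 4 decimals with trailing zeros trimmed ("0.143", "0.4665"),
  percentages at 2 decimals ("54.75%", "77.27%"), and the point-estimate
  display at whole percents ("86%"). JSON output always carries unrounded
  values.
* The trial-planner scans `n` linearly rather than bisecting: with a
  proportional criterion `x = ⌈τn⌉` the achieved confidence is sawtoothed
  in `n` for `τ < 1`, so bisection is unsound. At the default bound the
  scan is a few thousand `pbeta` calls — correctness is cheap here. The
  ceiling in `x = ⌈τn⌉` reflects that the criterion is a floor met with
  whole trials.

## What the simulation shows — and what it does not

`simulate_criterion()` draws each replicate's true mastery from the prior,
assesses it with `n` binomial trials, and retains replicates meeting the
criterion. Under exact-count conditioning the retained fraction below
`p_star` converges to `1 − b` and the retained mean to the posterior mean,
so the simulation is the frequentist mirror of the Bayesian statements —
a consistency check, not new evidence. Its population of students is by
construction the prior; real caseloads are not Jeffreys-distributed, so
empirical misclassification rates in a clinic can differ even when the
model is right for each individual. Alternative population priors can be
supplied to explore that robustness. The generator of synthetic
trial-level records (`generate_trials()`) likewise emulates a stationary,
independent responder with known `p`; it does not emulate acquisition
curves, prompting effects, or session-to-session drift, so round-trip
tests on its output validate bookkeeping and inference, not behaviour
change.

Default problem sizes in the shipped tests — posteriors up to `n = 20`
for the oracle sweep and 200,000 replicates for the Monte Carlo checks —
were chosen so each analytic quantity is pinned to well below its display
precision (Monte Carlo SE ≈ 0.001).

## Known limitations

* Single student, single skill component: no pooling or hierarchy across
  students, and no multiplicity handling across many components scored at
  once.
* The criterion-report text is fixed English phrasing by design, so that
  downstream golden tests can compare byte-for-byte.
* `mc` values at or below 1 are read as fractions and above 1 as percents;
  a genuine 1% criterion must therefore be given as `0.01`.
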