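# miebl

Bayesian selection of performance (mastery) criteria for discrete trial
training (DTT).

## The problem

In DTT a practitioner declares a skill component mastered when the student
answers at least a preset proportion τ of assessment trials correctly —
e.g. 8 of 10 trials for τ = 80%. But the observed proportion x/n is not
the student's *true* mastery level p, the latent probability of a correct
response to an arbitrary item from the skill component space. With the
small n typical of DTT sessions, meeting a criterion can carry surprisingly
little assurance about p. This package quantifies exactly how much: for
observed counts (n, x) it computes

> b = Pr(p ≥ p\* | x of n correct),

the posterior probability that true mastery meets the desired level p\*,
under the conjugate beta-binomial model with a Jeffreys Beta(½, ½) prior:

> p | x, n ~ Beta(x + ½, n − x + ½).

Tail probabilities, credible lower bounds and posterior means follow from
the regularized incomplete beta function and its inverse. The intended
users are behavior-analysis practitioners and researchers choosing mastery
criteria, and methodologists studying criterion operating characteristics.

## Worked example

Ten trials, desired mastery 90%, considering an 80% criterion:

```r
library(miebl)

tab <- criterion_table(10, p_star = 0.90, a = 0.05)
criterion_report(tab, mc = 80)
```

```
Performance criterion of 80% (8 out of 10 items)
If the student meets this criterion, then:
The probability that the true mastery is at least 90% is 0.143.
There is a 95% chance that the true mastery is at least 54.75%.
The average mastery of comparable students reaching this criterion is 77.27%.
```

So an 80% criterion on 10 trials gives only 14% confidence that the
student is truly at 90% mastery; a practitioner can be 95% sure only that
mastery exceeds about 55%, and students reaching this criterion average
about 77% true mastery — the gap between the observed 80% and this 77% is
selection bias, not skill loss.

Design questions invert the computation:

```r
min_trials_for_confidence(p_star = 0.90, b_target = 0.70, tau = 1)
#> Smallest design: n = 5 trials, criterion 100% (x = 5 correct)
#>   achieved Pr(true mastery >= 90%) = 0.7075
```

And Monte Carlo simulation confirms the operating characteristics: among
simulated students who get 5 of 5 correct, about 29% (= 1 − 0.71) in fact
sit below 90% true mastery:

```r
simulate_criterion(5, 5, p_star = 0.90, reps = 200000, seed = 1)
```

A command-line interface wrapping the same functions is installed at
`system.file("exec", "miebl", package = "miebl")` with subcommands
`table`, `report`, `compare`, `plan`, `simulate` and `score` (the last
aggregates trial-level CSV records per session or pooled).

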