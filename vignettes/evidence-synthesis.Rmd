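---
title: "Evidence synthesis as an odds calculus: model, screening and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence synthesis as an odds calculus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesodds)
```

## The model

`bayesodds` weighs two rival clinical hypotheses — H1, the test condition
is inferior to the control; H2, it is not inferior — against bodies of
study-level evidence. The guiding application is restorative dentistry
(high-viscosity glass-ionomer cement, HVGIC, versus silver amalgam in
permanent posterior teeth), but nothing in the calculus is specific to
it.

Every dataset contributes one *event*: an effect estimate comparing test
with control, either an odds ratio (binary restoration-failure outcomes)
or a standardised mean difference (continuous laboratory outcomes), with
a 95% confidence interval. Classification is purely interval-based: an
event supports H1 exactly when its CI lies strictly on the
control-favouring side of the null (1 for OR, 0 for SMD); a CI containing
the null, or lying on the test-favouring side, supports H2. This is
deliberately asymmetric — "not inferior" absorbs both equivalence and
superiority — and it makes statistical power a first-class concern:
underpowered datasets produce wide CIs that would spuriously pile up
support for H2, which is why the power screen below exists.

With tallies $n_{H1}, n_{H2}$ (total $N = n_{H1} + n_{H2}$) from the
prior evidence,

$$\mathrm{Odds}_{pre} = \frac{P(H1)}{P(H2)} = \frac{n_{H1}/N}{n_{H2}/N}
  = \frac{n_{H1}}{n_{H2}},$$

and with new-evidence sources $k = 1, \dots, K$,

$$LR = \prod_k \frac{P_k(E\mid H1)}{P_k(E\mid H2)}, \qquad
  \mathrm{Odds}_{post} = \mathrm{Odds}_{pre} \times LR.$$

Odds are always computed from raw counts, never from rounded
intermediate probabilities: 9 versus 8 events gives exactly $9/8 =
1.125$, which is displayed as 1.12 only at report time (two decimals,
half-to-even). A source judged too unreliable to discriminate between the
hypotheses enters the product as a *fixed* source with
$P(E|H1) = P(E|H2) = 0.50$ and contributes exactly 1; in the pipeline
this is the default treatment of the prior stratum
(`evidence1_equivocal = TRUE`), whose tallies still define the prior
odds. The product form assumes the sources are independent; where they
are only approximately so (an equivocal source sidesteps the issue by
contributing 1), the result should be read accordingly.

### Zeros and infinities

The calculus is ratio arithmetic, so zeros are meaningful, not numerical
noise. $P_k(E|H1) = 0$ legitimately drives $LR$ and the posterior to 0;
we let it propagate by default. The mirror case $P_k(E|H2) = 0$ has no
finite answer and is an error naming the offending source. A prior tally
with $n_{H2} = 0$ yields an explicit infinity, serialised as the string
`"inf"` in JSON reports. The indeterminate product $\infty \times 0$
raises an error rather than silently resolving either way. Optional
add-one (Laplace) smoothing — never applied silently — replaces each
tallied new-evidence count $n$ by $n + 1$, keeping every ratio finite for
sensitivity analysis; the prior tally is not smoothed, so the documented
prior odds are unchanged.

## Effect measures

For raw 2×2 failure tables the OR is the cross-product ratio with the
log-scale Wald interval, $\exp(\ln OR \pm z\,SE)$,
$SE = \sqrt{1/a + 1/b + 1/c + 1/d}$. A zero cell triggers the
Haldane–Anscombe correction (+0.5 to all four cells), applied only when
needed and flagged on the estimate — the conventional choice where the
method itself is silent. For continuous summaries the SMD uses the
pooled SD; the default flavor applies the small-sample factor
$J = 1 - 3/(4(n_1+n_2) - 9)$ (Hedges), with the uncorrected (Cohen)
value available via `smd_flavor = "cohen"` since extracted literature
values may be either. The test suite cross-checks both measures against
`metafor::escalc()` at 1e-10 relative tolerance (against the uncorrected
standardised difference for the SMD, because `metafor` applies the exact
gamma-function small-sample factor whereas this package implements the
stated closed-form approximation; the two agree only to about 1e-5).
The z-quantile always comes from `qnorm()` at the configured level, not
a hard-coded 1.96.

Direction matters: for failure outcomes a value above the null means the
test material fails more often, favouring the control; for a laboratory
strength measurement the reverse holds. Each estimate therefore carries a
`direction` field (`higher_is_worse_for_test` /
`higher_is_better_for_test`) that classification consults; evidence
tables must set it per row for laboratory outcomes.

## The power screen and per-trial selection

Pocock's two-proportion formula on the percentage scale,

$$N_P = \frac{P_1(100-P_1) + P_2(100-P_2)}{(P_2-P_1)^2} \times
  f(\alpha, \beta),$$

with $P_1 = P_2 + \delta$ and $\delta = 10$ percentage points by default,
gives the per-group size needed to detect a clinically meaningful
failure-rate difference at $\alpha = 0.05$, $\beta = 0.20$. A clinical
dataset is excluded when its combined evaluated size $N_T$ is *lower
than* $2 N_P$ — strict inequality, ties included — with $N_P$ never
rounded before the comparison. The default power factor is the tabulated
7.9 rather than the computed $(z_{0.975} + z_{0.80})^2 = 7.8489$, so
screening decisions reproduce published tabulations bit-for-bit;
`f_value = "computed"` switches to the closed form for sensitivity
analysis. Laboratory datasets are exempt from the screen: they are not
clinical investigations.

Two cases the formula's definitions do not cover needed decisions:

- **One-arm datasets.** $N_T$ is defined as test plus control combined,
  but uncontrolled one-arm studies have a single arm. We use that arm's
  evaluated total as $N_T$.
- **Control rate for HVGIC-only datasets.** $P_2$ is the amalgam arm's
  failure rate, which a test-material-only trial does not observe. The
  screen requires an explicit `reference_control_rate_pct`
  configuration key for such rows; there is deliberately no silent
  default.

After screening, each trial contributes at most one dataset:
meta-analysis rows outrank single datasets, then the longest follow-up
wins — avoiding duplication across follow-up reports of the same trial.
When a trial's longest follow-up is power-excluded, the next sufficient
dataset is automatically the longest surviving one.

One-arm datasets that survive screening enter the prior stratum through
*naive-indirect* pairing: an HVGIC-only trial is contrasted with an
amalgam-only trial as if the two had been arms of one study. This
reconstructs, on purpose, the methodologically weak comparison that
historic inferiority claims rested on; its unreliability is exactly why
the pipeline then weights the stratum as equivocal in the LR step. Pairs
are formed in table order; leftover unpaired rows are logged and counted
in the flow.

## The synthetic generator

`generate_evidence_table()` emulates the structure the analysis assumes,
not any historical dataset row-by-row:

- **RCT stratum**: two-arm trials with binomial failure counts; each
  trial is reported at every follow-up on the grid (12/24/36 months by
  default), with failures generated cumulatively — each interval adds
  new binomial failures among survivors at a constant interval hazard
  calibrated so the expected cumulative rate at the last follow-up
  equals the configured true rate. This gives the longest-follow-up
  selection rule real structure to act on. A configured fraction of
  trials (default 0.2) carries a meta-analysis flag.
- **Uncontrolled stratum**: one-arm trials of each material, binomial
  counts, follow-up at least 12 months.
- **Laboratory stratum**: per-trial true standardised effects drawn from
  $\mathcal{N}(\mu_{lab}, \sigma_{lab})$, arm summaries from
  unit-variance normal samples, direction written explicitly.

Defaults state the evidence base the analysis targets: equal 10% true
failure rates for both materials (the no-difference ground truth the
head-to-head literature supports), arm sizes 100–400 so a realistic
share of clinical datasets fails the 2·N_P screen, about ten trials per
stratum, and heterogeneous laboratory effects ($\mu_{lab} = 0$,
$\sigma_{lab} = 1$) reflecting a scattered in-vitro literature. One
integer seed drives everything through fixed per-stratum substreams, so
identical configurations give byte-identical tables.

What passing tests on synthetic data do and do not show: the generator
draws independent binomial/normal summaries with no publication bias, no
between-trial heterogeneity in the clinical strata, no dropout, no
misclassification of outcomes, and no correlation between arms. Tests
against it validate the calculus, the screening arithmetic and the
classification rule — not the epidemiological validity of any real
evidence base.

## Numerical and design choices

- Prior odds from raw counts (9/8 = 1.125), treating published
  two-decimal intermediates (0.53/0.47) as display rounding; the
  displayed value 1.12 matches either way.
- CI endpoints exactly at the null count as *containing* it
  (non-significant, hence H2) and are flagged as boundary cases —
  conservative toward non-inferiority.
- Validation is split from screening: the reader warns about
  uncontrolled rows with under 12 months of follow-up but does not drop
  them; inclusion criteria belong to screening configuration.
- The pipeline refuses, rather than guesses, whenever a required input
  is missing: no control rate for a one-arm clinical row, a one-arm row
  reaching direct effect computation, an indeterminate
  $\infty \times 0$.
- Reports round at two decimals, half-to-even, only at display/serialise
  time; all internal arithmetic is full precision.

Problem sizes in the test suite were chosen to make the Monte-Carlo
checks sharp but quick: 50 trials with 2,000-restoration arms for the
null-calibration check (~150 events), 1,000 random tables for the oracle
cross-check, and 500 randomised instances per algebraic property. One
subtlety of the calibration check: under equal true rates about 95% of
events are non-significant (nominal CI coverage), but the H2 share runs
slightly higher because the ~5% of spuriously significant events split
evenly and the test-favouring half also counts as H2 — the long-run H2
share is therefore ≈97.5%, and observed values near either figure are
consistent with a correct implementation.

## Known limitations

- The likelihood ratio treats sources as independent; dependence between
  strata is not modelled beyond the option of entering a stratum as
  equivocal.
- No density-based (continuous) Bayes factors, hierarchical priors or
  MCMC: the calculus is ratio-of-proportions arithmetic by design.
- Meta-analysis rows in evidence tables are consumed as reported; the
  package never re-pools study results.
- Exact (conditional/mid-p) OR intervals are not offered; classification
  relies on the reported or Wald-derived 95% CI only, with no
  multiplicity adjustment across events.
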