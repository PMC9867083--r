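---
title: "Isobolographic analysis of fixed-dose antiseizure drug combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isobolographic analysis of fixed-dose antiseizure drug combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesiso)
```

## The experimental setting

In the maximal electroshock seizure (MES) model, groups of mice receive
increasing doses of a drug and each animal is scored protected or not
protected against tonic hindlimb extension. The outcome of one experiment
is therefore quantal: per-dose counts `protected / n`. The potency of a
drug is its median effective dose, the ED50, estimated by fitting a
cumulative-normal ("probit") curve on log10 dose.

A practical question in epilepsy pharmacology is whether an add-on
compound (here, natural products such as scoparone, a coumarin, and
borneol, a monoterpenoid) merely contributes its own anticonvulsant effect
to a classic antiseizure medication (ASM) — *dose-additivity* — or
potentiates it beyond that — *synergy*. mesiso implements the fixed-dose
isobolographic transformation used to answer this: the adjunct is given at
a constant dose while the ASM is titrated, and the observed mixture
potency is compared with the potency predicted under exact additivity.

## The dose-response model

`fit_log_probit()` fits

$$P(\text{protect} \mid d) = \Phi\!\big(\beta\,(\log_{10} d - \mu)\big),
\qquad \mathrm{ED}_{50} = 10^{\mu},$$

by maximum likelihood. The fit is an ordinary binomial GLM with probit
link (`stats::glm`), reparameterised to $(\mu, \beta)$; the package's own
contribution is everything downstream of the fit, and the estimator is
verified in the test suite against a brute-force grid maximiser of the
binomial likelihood. The classic graphical log-probit workup of the older
bioassay literature coincides with this MLE asymptotically but involves
nomographic steps that are not fully reproducible; the MLE is.

Confidence limits are obtained by the delta method on $\mu$ (the log
scale, where the sampling distribution is closest to normal) and then
exponentiated, so they are asymmetric in mg/kg. The reported SEM follows
the summary-statistics convention of this literature: the 95% interval
width divided by $2 \times 1.959964$ (`sem_from_cl()`), on the arithmetic
mg/kg scale, because downstream tests operate on printed
$\mathrm{ED}_{50} \pm \mathrm{SEM}$ values.

The `n` attached to a potency is not the number of animals dosed but the
number at doses whose *fitted* protection probability lies between the 4th
and 6th probit, i.e. within $[\Phi(-1), \Phi(1)] \approx [0.16, 0.84]$
(`count_probit_window()`). Fitted rather than observed proportions decide
membership: an observed 0/8 at a dose near the window edge would otherwise
flip the count erratically between replicate analyses.

Degenerate inputs are refused with typed errors: assays that are all-0% or
all-100% (`degenerate assay` — no information about the ED50), and
perfectly ordered all-or-none response patterns (`separation` — the slope
MLE is unbounded). A quasi-separated fit whose information matrix is
numerically singular is reported as separation too.

## The isobolographic transformation

Let the ASM have solo potency $E_A$ and let adjunct $i$ be given at fixed
dose $d_i$ with solo potency $E_i$ (at its peak-effect pretreatment time,
15 min for the compounds studied here). Each fixed dose consumes the
fraction $d_i / E_i$ of a protective "dose unit"; under Loewe additivity
the ASM must supply the remainder, so on the total-mixture-dose scale

$$\mathrm{ED}_{50,\mathrm{add}} = \sum_i d_i +
  \Big(1 - \sum_i d_i/E_i\Big) E_A.$$

This total-dose convention is load-bearing: published mixture tables
report both the experimental and the additive ED50 as ASM component plus
fixed adjunct doses, and all eight published two-drug additive values this
package is validated against reproduce under this rule to printed
precision (asserted in the acceptance tests). The variance follows by the delta method,
$$\mathrm{Var} = (1-f)^2\,\mathrm{sem}_A^2 +
  \sum_i \Big(\frac{E_A d_i}{E_i^2}\Big)^2 \mathrm{sem}_i^2,$$
checked in the tests against a finite-difference Jacobian. When $f =
\sum_i d_i/E_i \ge 1$ the fixed doses alone already reach the additive
isobole and `additive_ed50_total()` refuses with `dose-exceeds-additivity`.

`classify_interaction()` then compares experimental and additive mixture
ED50s with the unequal-variance (Welch) t-test on summaries, degrees of
freedom by Welch–Satterthwaite with per-arm df $n - 1$. Published potency
tables name an "unpaired Student's t-test" but print fractional dfs; every
printed df of the source tables is reproduced exactly by the Welch form
computed from the printed SEMs, so that is what the package implements. A
non-significant difference (two-sided $p \ge \alpha$, default 0.05) is
additivity; a significant one is synergy when the experimental mixture is
the more potent, antagonism otherwise.

Two conventions of the table layout are exposed as options rather than
hard-coded: the animal count attached to the additive estimate,
$n_{\mathrm{add}} = n_A + n_{\mathrm{adj}} - 4$ with a multi-adjunct
mixture counting once (`n_rule`), and the fraction rendering, rounded half
away from zero to 2 decimals with the printed sum formed *after* rounding
("0.65 + 0.25 = 0.90", `sum_of_fractions_string()`). For three-drug
mixtures the package computes the documented fraction rule $f = \sum_i
d_i/E_i$; the published three-drug additive point values imply different
(underivable) adjunct fractions, so when reproducing those tests the
published additive values are supplied as inputs and the report JSON
carries a `fraction_mismatch` flag where the fraction sum is far from 1.

## Summary-statistics inference

All group comparisons are computable from (mean, SEM, n) triples, because
that is all a published potency table contains:

* `welch_from_summary()` — the Welch t described above;
* `anova_from_summary()` — one-way ANOVA with $SD_i =
  \mathrm{sem}_i\sqrt{n_i}$, between-group SS about the size-weighted
  grand mean; identical to `aov()` on raw data (asserted in the tests);
* `tukey_kramer_from_summary()` — all-pairs studentized-range comparisons
  on the pooled MSW (the Kramer form for unequal $n$), `stats::ptukey`;
* `dunnett_from_summary()` — many-to-one comparisons with adjusted
  two-sided p from the equicorrelated multivariate-t distribution
  (correlations $\lambda_i\lambda_j$, $\lambda_i =
  \sqrt{n_i/(n_i+n_0)}$), evaluated by `mvtnorm::pmvt` under a fixed
  internal RNG state (seed 20230111, absolute tolerance $10^{-6}$) so
  results are reproducible call to call. Both post-hoc procedures are
  cross-checked in the tests against independent Monte-Carlo oracles of
  the null max-statistic distributions (within 0.01).

`compare_brain_levels()` applies the ANOVA + Dunnett pair to total-brain
drug concentration groups (µg/g, default 8 animals per arm). Brain
figures in this literature display mean ± SD; the group summaries carry
SD and convert to SEM internally. Normality is assumed and no outliers
are removed.

## The synthetic-data generator

The generator exists so that every stage is testable without animal data.
Its defaults are the study conditions of the experiments the package
models:

* groups of 8 mice; 4-dose ladders geometrically spaced by $\sqrt 2$ and
  centred on the true ED50 (the printed solo dose ranges have this span);
* true ED50s from the published time-courses: scoparone 199.8/277.7/256.5/
  320.1 mg/kg and borneol 255.4/315.0/370.8/448.1 mg/kg at 15/30/60/120
  min; CBZ 9.52 (30 min), PHT 8.71 (120 min), PB 28.85 (60 min), VPA
  292.0 mg/kg (30 min);
* a common probit slope $\beta = 6$ probits per log10 dose. The raw
  quantal data behind the published potencies are not printed, so the
  slope is a modelling choice made once: MES dose-response curves are
  steep, and $\beta = 6$ reproduces the printed SEM scale (about 5–10% of
  the ED50 at these group sizes);
* brain arms of $n = 8$ with a 10% coefficient of variation, control mean
  20 µg/g and treated/control ratios 1.00/1.39/1.50 (the phenobarbital
  scenario's reported percent changes). The control mean is a synthetic
  scale choice; only ratios are identifiable from the published percent
  changes, and `percent_change_vs_control()` is scale-invariant.

Randomness is organised as one master integer seed from which every
(compound, time, dose) group derives its own 31-bit sub-stream via a
string hash, so adding a dose group or drawing assays in a different
order never changes any other group's data, and the generator never
perturbs the caller's RNG state.

Combinations are simulated from an effective-ED50 model: with adjunct
fraction $f$ and synergy parameter $s$, the ASM's ED50 in the mixture is
$E_A (1 - f(1+s))$. $s = 0$ is exact Loewe additivity — the null under
which the classifier's type-I error is measured — and $s > 0$ shifts the
mixture beyond additivity. This is the minimal generative model consistent
with the isobole definition; the study itself reports only endpoint ED50s,
so no richer combination-response model is identifiable from it.

What the generator does *not* emulate: litter or day effects, between-
group heterogeneity of the slope, pharmacokinetic time-courses of the
adjuncts (the published first-order brain elimination of scoparone has no
usable parameters), or any toxicity censoring. Passing simulation-based
tests therefore demonstrates correctness of the statistical machinery
under the stated model, not robustness of the MES assay itself.

## Operating characteristics, problem sizes and numerical choices

The test suite measures the package's operating characteristics at desk
scale, sizes chosen to estimate each rate to a useful precision:

* ED50 confidence-limit coverage over 200 simulated assays (4 doses × 8
  mice), required within [88%, 99%];
* classifier type-I error over 500 simulated studies (three probit fits
  each) under exact additivity, required within [2%, 9%]; measured at
  about 4%, slightly below the nominal 5% because the prescribed Welch t
  with df ≈ 30 is applied to delta-method SEMs that are nearly exact —
  the procedure is the published one, so the mild conservatism is kept;
* synergy detection rate non-decreasing over $s \in \{0, 0.2, 0.4, 0.6\}$
  at 400 replicates per level, using a valproate + borneol design with a
  large adjunct fraction ($f \approx 0.49$) so the power curve spans the
  band between floor and ceiling;
* post-hoc adjusted p-values against $10^5$-draw Monte-Carlo oracles.

Numerical details: the probit GLM iterates to a $10^{-12}$ deviance
tolerance (maximum 200 iterations) and is deterministic; ties in the
probit window are included (closed interval); `round_half_up()` implements
the half-away-from-zero table rounding; p-values print to 3 decimals with
a `<0.0001` floor; significance markers are `*`, `**`, `***` at 0.05,
0.01, 0.001. The weighted ED50-on-time trend test (`ed50_time_trend()`)
uses weights $1/\mathrm{sem}^2$, falling back to equal weights when any
SEM is missing, and calls a direction only at $p < 0.05$ — published
time-course analyses of this design assert a linear trend without naming
the statistic, so the package makes no claim to reproduce their p-values.

## A worked example

```{r example}
pb <- potency_summary("PB", 28.85, 1.89, 16)
sco <- fixed_dose_component("scoparone", 50, 199.8, 0, 16)
add <- additive_ed50_total(pb, sco)
add

# the experimentally determined mixture potency, total-dose scale
classify_interaction(68.71, 1.88, 16,
                     list(ed50_add_total = add$ed50_add_total,
                          sem_add = 2.44, n_add = add$n_add))
```

```{r simulated}
cfg <- mes_sim_config(seed = 101)
assay <- simulate_assay(cfg, "PB", 60)
fit_log_probit(assay)
```

## Known limitations

Fixed-ratio isobolography, Loewe interaction indices, Bliss independence
and Chou–Talalay combination indices are out of scope, as are dose-response
links other than the probit and the chi-square heterogeneity corrections of
the classical nomographic workup. SEM propagation for additive estimates
cannot be validated against the published tables (the adjunct SEMs behind
them are not printed), so published additive SEMs are accepted as inputs
when reproducing published tests.
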