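---
title: "Checkable simulation studies: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Checkable simulation studies: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simtrace)
```

`simtrace` runs Monte Carlo simulation studies in a way that keeps every
intermediate object inspectable and every repetition replayable. This
vignette explains the statistical content of the packaged study, the
design decisions behind the engine, the numerical choices, and what the
test suite does and does not demonstrate.

## The data-generating mechanisms

Each repetition draws n individuals (default 500) as

$$C_i \sim N(0,1), \quad
E_i \sim \mathrm{Bern}\{\mathrm{expit}(\alpha_0 + \alpha_C C_i)\}, \quad
D_i \sim \mathrm{Bern}\{\mathrm{expit}(\beta_0 + \beta_E E_i + \beta_C C_i)\},$$

and then a missingness indicator for the confounder,

$$M_{C,i} \sim \mathrm{Bern}\{\mathrm{expit}(\gamma_0 + \gamma_E E_i +
\gamma_D D_i + \gamma_C C_i)\}.$$

The estimand is $\theta = \beta_E$, the E–D log odds ratio conditional
on C, with true value 0 by default: the design deliberately makes E
causally inert so that full-data analysis, and complete-case analysis
under MCAR, have *known answers* (no bias, nominal coverage) against
which the machinery can be checked. Because $\alpha_C, \beta_C > 0$, C
confounds: the unconditional D–E log odds ratio is positive even though
E does nothing, and `large_sample_check()` verifies this sign, refits
both generating models to a single very large data set (default
N = 100000) and reports truth-in-CI verdicts per coefficient.

Default coefficients. The study fixes $\alpha_0 = \beta_0 = -1$,
$\alpha_C = \beta_C = 1$, giving exposure and outcome prevalences near
30%. Rarer exposure or outcome invites random positivity violations at
n = 500 — complete-case subsets with no events or no exposed — which are
a pathology this package *detects and handles* but which should not
dominate the headline study. Missingness intercepts are set so each
mechanism deletes roughly 30% of C: MCAR uses
$\gamma_0 = \mathrm{logit}(0.3)$ alone; MAR adds
$\gamma_E = \gamma_D = 1$ around $\gamma_0 = -1.5$; MNAR uses
$\gamma_0 = -1, \gamma_C = 1$. The constructor enforces the mechanism
taxonomy (MCAR permits no dependence; MAR permits dependence on the
always-observed E and D only; MNAR may depend on C itself). All values
are configurable per [dgm_spec()].

What the generator emulates — and what it does not. It reproduces the
confounding-with-missing-confounder structure at realistic prevalences
and missingness, with a single Normally distributed confounder and
logistic link everywhere. It does not emulate multivariate missingness,
missingness in E or D, non-Normal or multiple confounders, measurement
error, or clustering. Tests passing under this generator therefore show
that the *machinery* (engine, estimators, pooling, measures, Monte Carlo
errors) is correct under these conditions; they do not certify multiple
imputation's behaviour for real data whose missingness process is
unknown — indeed the MNAR arm exists precisely to show the method
failing when its assumption fails.

## Analysis methods

All three methods fit logistic regression of D on (E, C) and report the
E coefficient, its SE, and a confidence interval.

* **full** — every row, using the true C. Only possible inside a
  simulation; included as the known-answer benchmark.
* **cca** — rows with $M_C = 0$.
* **mi** — m = 20 proper Normal-linear imputations of C given (E, D):
  among observed rows regress C on (1, E, D); draw
  $\sigma^{*2} = \mathrm{RSS}/\chi^2_{n_{obs}-3}$, then
  $\beta^* \sim N(\hat\beta, \sigma^{*2}(X'X)^{-1})$, then fill each
  missing C as $x'\beta^* + \sigma^* z$. Pooling uses Rubin's rules
  ($T = W + (1+1/m)B$) with Barnard–Rubin degrees of freedom at
  complete-data df $= n - 3$.
* **cca_firth_hybrid** — cca with an automatic Firth backup (below).

Design decisions worth recording:

* The outcome D is a predictor in the imputation model. Omitting the
  analysis outcome from an imputation model biases the association of
  interest towards the null; this is the standard congenial choice for
  this analysis model. The Normal-linear form is nevertheless mildly
  misspecified here (the true C given E, D is a tilted Normal), which is
  visible only as small-sample imperfection, not as first-order bias
  under MCAR/MAR.
* m = 20 imputations balances Monte Carlo noise in the pooled estimate
  against runtime; B is estimated from 20 draws, which is ample for
  point performance measures at 1000 repetitions.
* Confidence intervals are Wald with z quantiles for full and cca, and
  t with Barnard–Rubin df for MI. Coverage targets at the 95% level are
  insensitive to this choice at n = 500, but the BR correction is the
  defensible default for pooled variances.

## Separation, failures, and hybrids

Sparse data sets can make the complete-case fit degenerate: no events,
no non-events, no exposed or no unexposed rows among the analysis
subset, under which the ML estimate is infinite. `detect_separation()`
flags zero margins of the E×D table directly, plus a divergence
criterion |coefficient| > 10 — pathological separated fits in common
software land in the teens with standard errors in the thousands, while
genuine log odds ratios of that size do not occur in this design. Any
separation or non-convergence becomes a `failed:<code>` outcome row;
`run_method_guarded()` additionally converts *any* raised condition into
such a row, so a study always yields exactly one row per
mechanism × method × repetition (failures included — the failure count is
itself a performance measure, reported by `failure_rate()` and excluded
from the moment-based measures).

`fit_logistic_firth()` maximizes the Jeffreys-penalized likelihood
$\ell(\beta) + \tfrac12 \log \det I(\beta)$ by modified-score Newton
iteration with hat-value corrections; its estimates are finite under
separation, and in a saturated 2×2 reduce to the add-half-to-each-cell
log odds ratio. `hybrid_with_backup()` wires it in as an automatic
backup (trigger defaults: separation, |estimate| > 10, se > 100), with
`backup_used` recorded so the performance table describes the hybrid
procedure honestly.

Numerical settings: IRLS tolerance 1e-8 with a 100-iteration cap for
both engines; the Firth update is damped to a maximum step of 5 per
coordinate. Degenerate inputs (too few rows, singular designs, zero
empirical SE, all-failed cells) are reported as missing values or coded
failures, never as exceptions.

## The engine and random-number states

One random stream drives everything. Within a repetition the draws are
consumed in fixed order (C, then E, then D, then M_C), and the stream is
*never* re-seeded inside the loop — the classic bug in which every
repetition replays the first one's data is instead detected after the
fact by `verify_rep_distinctness()`, which flags any two repetitions of
the same cell with identical (estimate, se).

Before each repetition's generation the engine serializes
`.Random.seed` into a base64 token (format tag `r-serialize-b64-v1`,
written into the states CSV header); a second token is captured
immediately before the first stochastic analysis (MI), so both the data
set and the stochastic analysis can be replayed exactly. The spec-level
alternative — storing every simulated data set — is available by simply
writing each recreated data set out, but states are cheap and exact, so
they are the default. One analysis state per repetition is stored (not
one per method); if several stochastic methods were configured, replaying
the second one exactly would additionally require re-running the first,
and this limitation is deliberate and documented.

`fixed_full_data = TRUE` reproduces a known pitfall: generating one full
data set per mechanism and deleting afresh each repetition. The
model-based SE then includes sampling variation of the full data that
the empirical SE cannot contain, so the two disagree grossly — the
packaged test shows the model-based SE exceeding the empirical SE by
well over 50%. For recreatability under this flag the engine stores one
extra state row with `rep_id = 0` per mechanism (the state before the
shared generation), and `recreate_dataset()` replays shared generation
and per-repetition deletion in sequence.

## Performance measures and Monte Carlo errors

For each mechanism × method cell, over the non-failed repetitions:
bias $\bar{\hat\theta} - \theta$ (MCSE $S/\sqrt{n}$); empirical SE $S$
(MCSE $S/\sqrt{2(n-1)}$); model-based SE
$\sqrt{\overline{\widehat{se}^2}}$, the root mean square rather than the
plain mean so its square unbiasedly estimates the mean estimated
variance (MCSE $\sqrt{\mathrm{Var}(\widehat{se}^2)/(4 n\,
\mathrm{modSE}^2)}$); relative error
$100(\mathrm{modSE}/\mathrm{empSE} - 1)$ with a delta-method MCSE
treating the components as independent; coverage and rejection rates in
percent with binomial MCSEs. Inside `performance_table()` the rejection
rate is computed as exclusion of the null value from the stored
interval — identical to the two-sided Wald test at the interval's df, and
robust to the fact that the estimates CSV schema does not carry df.

`mc_compatibility_check()` encodes the first question to ask of any
surprising result: is it within 2 MCSE of what was expected? The margin
is strict (exactly 2 MCSE is "not compatible"), a tie-break that matters
only at measure-zero boundaries but must be fixed for testability.

## Zip plots and outlier flags

`zip_plot_data()` ranks each cell's intervals by the two-sided Wald
p-value against the true value, least compatible first, ties broken by
repetition id (the orientation and tie-break are presentation
conventions fixed here for determinism). The non-covering fraction
agrees with the coverage measure *exactly*, by construction, and the
test suite asserts the integer-count identity. Zero-SE rows have no
defined p-value and are excluded with a warning count.

Outlier flags default to |estimate| > 10, se > 100, se < 1e-8. The
first two catch divergent separated fits; the third catches software
that silently drops a separated covariate and reports exact zeros. All
are configurable, and an empty rule set flags nothing.

## Problem sizes in the test suite

The suite exercises the full study at its defining size — 3 mechanisms ×
3 methods × 1000 repetitions of n = 500 with m = 20 — plus a 400-
repetition fixed-full-data run, large-sample checks at N = 100000, and
property checks on small constructed fixtures. The grid-refinement
oracle used against both fitting engines evaluates the raw likelihoods
on successively zoomed lattices and shares no code with the IRLS paths.
These sizes were chosen so the whole suite completes in a few minutes
while leaving every Monte Carlo comparison with margins (2 MCSE at 1000
repetitions) that the known answers meet comfortably.

## Known limitations

* Missingness is univariate (C only) and the imputation engine is
  Normal-linear; predictive mean matching and multivariate schemes are
  out of scope.
* Exact conditional logistic intervals are not implemented; Firth
  penalization is the packaged answer to separation.
* State tokens are portable across machines running the same R RNG
  kinds, and versioned in the file header, but are not a
  cross-language format.
* Single-stream execution is serial by design: parallel repetition
  scheduling would break the stored-state replay semantics and is
  deliberately not offered.
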