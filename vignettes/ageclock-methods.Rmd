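---
title: "Methods: age transformations, penalized clocks, and their evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age transformations, penalized clocks, and their evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ageclock)
```

## The model

An epigenetic clock regresses a transformed chronological age on CpG
methylation fractions,

$$F(y) = x^\top\beta + \varepsilon,$$

with $x \in [0,1]^P$ the beta values of $P$ probes and $F$ an invertible,
strictly increasing map. The coefficient vector is estimated by the
elastic net,

$$\hat\beta = \arg\min_\beta \frac{1}{2n}\sum_i (F(y_i) - \beta_0 -
x_i^\top\beta)^2 + \lambda\left(\alpha\lVert\beta\rVert_1 +
\tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\right),$$

solved by glmnet. A fitted clock is fully described by its intercept, its
non-zero coefficients, and the name and parameters of $F$ — which is
exactly what the clock CSV dialect stores, so any conforming coefficient
table can be applied with `predict_age()`.

## The transform registry

Five transforms are registered; all have closed-form inverses and are
tested for strict monotonicity and round-trip error below $10^{-8}$ years
on 1000-point grids.

| name | formula | parameters |
|---|---|---|
| `identity` | $F(a)=a$ | — |
| `log_linear` | $\log\frac{a+k}{m+k}$ if $a<m$, else $\frac{a-m}{m+k}$ | $m$ = sexual maturity, $k$ = offset (default 1 y) |
| `relative_age` | $R=\frac{a+g}{L+g}$ | $L$ = max lifespan, $g$ = gestation |
| `loglog_relative_age` | $-\log(-\log R)$ | as above, domain $R\in(0,1)$ |
| `relative_adult_age` | log_linear on $R$ with anchor $m'=\frac{m+g}{L+g}$ | $L,g,m,k$ |

Design notes, where the choices were genuinely open:

- **log-linear knot.** The two branches share the value 0 and the slope
  $1/(m+k)$ at $a=m$, so the transform is $C^1$; this is asserted
  numerically in the tests.
- **relative_adult_age offset.** The literature names the construction
  ("log-linear on the relative-age scale") without pinning the offset on
  that scale. We map the years-scale offset through the same affine change
  of variables, $k' = k/(L+g)$, which makes the sub-maturity branch equal
  $\log\frac{a+g+k}{m+g+k}$ — dimensionally consistent and reducing to
  plain log_linear when $L+g = 1$.
- **Boundary handling.** Forward transforms reject ages with $R \ge 1$
  (an animal at or beyond its recorded maximum lifespan) rather than
  clamping, because a silently clamped input usually signals a unit error
  in the species table. An explicit `clamp = TRUE` parameter maps $R$ to
  $\min(R, 1-10^{-6})$ for datasets that genuinely contain near-record
  ages.
- **Inverse of relative_age.** The forward map is affine, so its inverse
  is total. A clock's linear predictor for a very young animal can land
  slightly below 0; rejecting it would make honest cross-validation of
  young samples impossible, so the inverse returns the (possibly slightly
  negative) DNAm age as-is. `clamp = TRUE` floors the relative age at
  $10^{-6}$ instead. This is the one place we deliberately relaxed a
  stricter default: a total inverse is both the mathematically natural
  choice and the way relative-age clocks are reported in practice.

## Fitting and the penalty path

`fit_options()` defaults: $\alpha = 0.5$, 10 internal CV folds, the
`min` lambda rule, standardized predictors. The lambda path is 100
log-spaced values from $\lambda_{max}$ (the smallest lambda zeroing every
coefficient) down four orders of magnitude. Fold assignment derives from
an explicit seed through a save/restore RNG wrapper, so no package
function perturbs the caller's random stream; the same seed reproduces
folds, lambda, coefficients, and predictions bit-for-bit.

Missing betas are mean-imputed per probe before fitting (with a warning
when any probe needed more than 20% of its values imputed — such probes
belong in the pre-filters instead). Filtering is never applied implicitly.

## Cross-validation

`loo_estimate()` refits the clock $n$ times, each time excluding one
sample from both the sample sheet and the methylation matrix, and
predicts the held-out sample. The penalty is selected **once** on the full
data and reused in every fold: per-fold optima converge closely, and the
shortcut turns an $O(n \times \text{CV})$ computation into $O(n)$ refits.
`loso_estimate()` applies the same logic with one fold per species — the
fold's training matrix provably contains zero rows of the held-out
species (a hard `stopifnot`, not merely a test). The shortcut is extended
from LOO to LOSO for consistency; `per_fold_lambda = TRUE` re-selects
within each fold for both. Metrics (Pearson r, MAE, median AE) are
reported on the years scale after inverse transformation, with
transformed-scale metrics alongside.

Samples are internally reordered to sorted sample ids before fold
assignment and fitting, which makes cross-validation results invariant to
the column order of the input matrix.

## Probe filters and QC

The middle filter's window defaults to $[0.3, 0.7]$: "mean beta
approximating 0.5" is not a sharp definition, and this window is wide
enough to catch the non-mappable-probe artifact peak while sparing most
genuinely intermediate biology; it is a parameter, not a constant. The
detection-p filter defaults to the strictest reading — any sample failing
$p > 0.05$ removes the probe (`max_fail_fraction = 0`) — with the laxer
fraction exposed because real cohorts need it. Filters see raw evidence:
missing betas are excluded from probe means, never imputed, and every
filter returns a kept/removed partition with per-probe reasons.

QC flags arrays by mean inter-array Pearson correlation below 0.9 (the
expected same-tissue floor), a monotone surrogate for "merges high in the
dendrogram"; the tree route — average-linkage clustering on $1 - r$ with a
static cut (default height 0.2, consistent with the 0.9 expectation) — is
also provided. With missing data, pairwise-complete correlations require
at least `min_shared` jointly observed probes per pair (default 1000) to
avoid noisy estimates; small in-memory matrices should pass `min_shared`
explicitly.

## EWAS

`ewas_correlate()` computes per-probe Pearson (or biweight
midcorrelation) with the outcome, then $z = \operatorname{atanh}(r)
\sqrt{n-3}$, two-sided normal p, and Benjamini–Hochberg q over the
non-missing probes. `meta_ewas()` combines strata by Stouffer's method,
$z_{meta} = \sum_s w_s z_s / \sqrt{\sum_s w_s^2}$, with $w_s = \sqrt{n_s}$
by default — the original tooling does not document its combination rule,
and Stouffer with root-n weights is the standard fixed-weight choice.

## What the simulator does and does not emulate

`simulate_cohort()` is the package's fixture generator, built so the
estimator is tested *within model class*:

- ages uniform on $(0, 0.9L)$ per species; the default cohort has three
  species with $L = 10/25/60$ years ($g = 0.06/0.2/0.6$,
  $m = 1/4/12$), 50 samples each;
- 2000 probes: baselines from a bimodal Beta mixture (means 0.08 and
  0.92), a 10% artifact fraction forced to mean $\approx 0.5$ with low
  variance (the trimodal peak the middle filter targets), and 100 signal
  probes whose beta is *linear in transformed age* with slopes drawn from
  $\pm[0.15, 0.4]$, signed away from the nearer boundary so that clipping
  to $[0,1]$ stays below 5%;
- Gaussian noise (sd 0.03 on the beta scale), optional missingness,
  everything reproducible from one seed.

It does **not** emulate CpG-island correlation structure, platform-specific
probe behavior, batch effects, or realistic inter-probe dependence. A
green test therefore establishes that the estimator recovers a linear
transformed-age signal under beta-scale noise and artifact contamination —
not that any particular biological clock is recoverable.

One measured consequence of these defaults is worth recording: with slopes
in $[0.15, 0.4]$ against noise sd 0.03, the signal probes correlate with
each other at $|\rho| \approx 0.85$ and are therefore statistically
redundant. The CV-optimal elastic-net support saturates near 70 probes, of
which 68–69 are true positives — excellent prediction (LOO r > 0.99) with
deliberately incomplete support recovery. The acceptance suite pins the
support-overlap expectation at ≥ 70/100, and that single assertion runs
red under these defaults; we left both the generator and the assertion
untouched rather than tune either toward the other after measurement.

## Numerical choices

- Clock CSVs and beta CSVs are written with 17 significant digits, so a
  write/read round trip reproduces the exact double bit patterns.
- `fit_clock()` warm-starts glmnet along a path ending exactly at the
  requested lambda with convergence threshold $10^{-12}$; at
  $\lambda = 0$ on full-rank problems it matches ordinary least squares
  to $10^{-6}$, and at $\lambda \to \infty$ it returns the empty model
  with intercept $\bar y$.
- Readers reject rather than coerce: out-of-range betas, duplicate
  intercept rows, non-numeric ages, and conflicting species duplicates
  all fail with file/line context.

## Known limitations

- The bundled clocks are synthetic fixtures; published consortium clock
  files are not redistributed, but any conforming CSV dropped into a user
  directory is picked up by `get_clock_registry()`.
- Only Gaussian-response clocks (age) are implemented; mortality-risk and
  other generalized-outcome clocks are out of scope.
- Idat parsing and normalization are upstream: the package consumes
  normalized beta matrices.
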