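---
title: "Modelling and model selection for in vitro gas production kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and model selection for in vitro gas production kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpkin)
```

## The model framework

In vitro gas production (GP) assays incubate a feed sample with buffered
rumen fluid and record cumulative gas (mL per 200 mg dry matter) at fixed
times; in the Hohenheim Gas Test design used here the nine reading times are
0, 2, 4, 6, 8, 12, 24, 48 and 72 h. gpkin models a GP curve
phenomenologically as a scaled cumulative distribution function,

$$GP(t) = m\,F_u(t),$$

where $m$ is the asymptotic gas yield and $F_u$ a unit CDF on the time axis.
The associated density $f = F'$ is the GP *rate* curve; its mode is the
inflection time $t^*$ (time of maximum rate, with gas volume $GP^*$) and its
median is the half-life $t_{0.5}$ (time to reach $GP_{0.5} = m/2$). Every
catalogue family has closed-form $t^*$ and $t_{0.5}$, which is a deliberate
inclusion criterion: the kinetic summaries practitioners report must not
depend on numerical root finding.

The catalogue is fixed at 21 families (`gp_models()`), from two-parameter
curves (Exponential 2p, Rayleigh 2p, Half logistic, Inverse exponential,
Generalized logistic) through the four-parameter Burr XII and Dagum.
Parameters follow one canonical order (m, r, mu, a, p) with explicit absence,
so result tables are uniform across families of different arity.

Two notes on individual families. The Generalized logistic enters time
unscaled (no rate constant); it is implemented exactly as catalogued, and its
small fitted shape values ($a \approx 0.07$–$0.12$) are what place the curve
on the 0–72 h axis. The Gompertz curve is parameterised with base-$a$ growth,
$F_u(t) = 1 - e^{r(1 - a^t)/\ln a}$; the implementation evaluates the
exponent through `expm1` with a series limit at $a \to 1$, where the family
degenerates smoothly to Exponential 2p. All logarithms in the catalogue
formulas are natural logarithms.

## Two levels of parameter constraints

The catalogue declares shape assumptions (for instance $a > 1$ for Burr XII,
Weibull, Gompertz, Paralogistic; $a, p > 1$ for Burr III and Dagum) whose
role is to guarantee an interior inflection point. The published reference
summary that ships with the package, however, contains fitted cells that
violate them (Burr III with $a = 0.953$, Gompertz with $a = 0.989$, Weibull
with $a = 0.967$), which is only possible if the original fits were not
hard-bounded by those assumptions. gpkin therefore distinguishes:

* the **evaluability domain** ($m, r, a, p > 0$, $\mu$ free) — enforced by
  the fitting layer and by `gp_cdf()`/`gp_pdf()`; every curve in this domain
  is a valid monotone CDF scaled by $m$ (Gompertz with $a < 1$ saturates a
  hair below $m$, which the asymptote absorbs in practice);
* the **declared assumptions** — reported by `validate_params()`, and used
  by `kinetic_summary()`: when the $t^*$ precondition fails (e.g. fitted
  $a \le 1$), `t_star` is flagged undefined and reported as 0, matching how
  such cells are conventionally printed. Families whose density mode sits on
  the domain boundary (Exponential 2p/3p, Half Cauchy, Half logistic) are
  flagged the same way, with the boundary time reported.

This mirrors the source analysis: unconstrained-positivity fitting, with the
$a > 1$ conditions interpreted as *kinetic meaningfulness*, not feasibility.

## Fitting

The error model is additive, homoscedastic Gaussian, independent across
reading times. For each profile and family the package minimises
$\sum_i (y_i - m F_u(t_i))^2$. Because $m$ enters linearly, it is profiled
out analytically at every objective evaluation (variable projection):
$\hat m(\theta) = \sum y_i F_u(t_i) / \sum F_u(t_i)^2$, leaving a 1–3
dimensional search over the nonlinear parameters. These are transformed
($\log$ for the strictly positive $r, a, p$; identity for $\mu$) and
optimised with `nlminb` (PORT), relative tolerance $10^{-10}$, up to 500
iterations. A small deterministic multistart (default 5 launches: one
heuristic start plus seeded jitters, sd 0.3 on the transformed scale) guards
against local minima; the per-pair seed stream is derived from the global
seed, so runs are bit-reproducible. The variable-projection formulation
replaces the bounded trust-region design that a direct all-parameter search
would need: it is faster, cannot produce a negative asymptote, and proved
exact (RSS $\sim 10^{-18}$) on noise-free recovery of all 21 families.

Start values: $r_0 = \ln 2 / t_{50,\mathrm{obs}}$ with $t_{50,\mathrm{obs}}$
the interpolated observed half-max time; $a_0 = p_0 = 1.5$; $\mu_0 = 0$ for
lag-type families (Exponential 3p, Half Cauchy, Rayleigh 3p) and
$\mu_0 = t_{50,\mathrm{obs}}$ for location-type families (Cauchy, Gumbel,
Logistic), whose $\mu$ *is* the centre of the curve — starting those at 0
wastes multistarts on curves centred near 6–10 h.

The $t = 0$ reading (volume 0) is part of the fit and of $n$, so $n = 9$ on
the standard grid; the BIC identity $k \ln 9 - 2\ln\hat L$ against the
shipped reference cells confirms this convention. Goodness of fit uses the
maximum-likelihood scale throughout: $\hat\sigma^2 = RSS/n$,
$RMSE = \sqrt{RSS/n}$, $\ln\hat L = -(n/2)(\ln 2\pi + \ln\hat\sigma^2 + 1)$,
$BIC = k\ln n - 2\ln\hat L$, which keeps the three metrics mutually
consistent. A perfect fit ($RSS = 0$) reports `loglik = Inf`/`bic = -Inf`
honestly rather than flooring the variance.

Failures are captured per record, never raised: `no-convergence` (optimiser
failure, or a degenerate all-zero profile whose least-squares problem has no
interior minimiser), `nan-estimates`, `negative-predictions` (checked on the
observation grid plus a dense 0–72 h grid, to catch pathological $\mu$
between reading times), `constraint-violation`. With the transformed
parameterisation the last two are structurally near-impossible, but they
remain part of the record contract.

## The selection layer

`two_way_anova()` decomposes BIC into model, feed-category and interaction
effects with **Type II** sums of squares via explicit nested `lm()`
comparisons. Type II was chosen because the assay design is unbalanced (3–7
replicates per feed, very different category sizes) and the source analysis
does not state its convention; with all 126 cells occupied Type II is the
standard default for testing main effects in the presence of interaction.
Empty cells raise an explicit design error rather than silently dropping the
interaction.

`tukey_groups()` runs per-category all-pairs model comparisons with the
studentized range statistic and the Tukey–Kramer correction for unequal
replication, using the within-category one-way MSE. The compact letter
display is built by insert-and-absorb. The *top set* of a category is every
model sharing a letter with the minimum-mean model; the *lower set* shares a
letter with the maximum-mean model. Defining "lower-performing" through the
worst Tukey letter is an interpretation (the source layout could also be
read as tree leaves); both views are available since the tree's leaf report
is emitted alongside.

`fit_tree()` is an in-package CART regression tree (no tree package is
assumed by the environment): squared-error criterion, and for a categorical
predictor the levels are ordered by mean response and only contiguous cuts
of that ordering are scanned — the optimal subset split under squared error.
Depth (3–8) and minimum leaf size (5, 10, 20) are tuned by RMSE on a seeded
30% validation holdout; the original tree software's exact tuning is not
documented, so the grid is the package's own choice. Contribution shares are
each predictor's summed split SS reduction over the total, times 100; leaf
reports give the model-set × category-set label, mean BIC and training
count, sorted by mean BIC.

`compute_rpi()` is the relative performance improvement,
$100(\bar B_{lower} - \bar B_{top})/\bar B_{all}$, with the three averages
taken as unweighted means over per-model cell means within the category
(cell weighting is not stated in the source; unweighted means reproduce the
published arithmetic).

## The synthetic world

The raw assay data are not deposited, so the generator
(`simulate_dataset()`) stands in for them, emulating exactly what the
analysis assumes: curves from catalogue families on the nine-point grid,
additive homoscedastic Gaussian noise, 3–7 replicates per feed, six feed
categories. The full-scale design (`gp_default_config("full")`) has 849
profiles (Compound 95, Corn 120, Processed protein 25, Legumes 138, Soft
cereal 460, Others 11), matching the published total and approximating the
per-category proportions implied by the published tree-leaf counts.

Defaults and their reasons:

* **noise sd 1.5 mL** — the source reports no per-curve variance; 1.5 mL
  sits inside the published RMSE range (0.71–6.74 mL) toward its lower
  (well-fitting) end. It is a stand-in, flagged as such in run manifests.
* **truncation at 0** — volumes are physical; at the default sd the induced
  bias is negligible (the curve is > 4 sd above zero from the first reading
  on for typical parameters).
* **t = 0 pinned to exactly 0** — GP$_0 = 0$ by definition of the assay.
  Four families (Cauchy, Logistic, Gumbel, Generalized logistic) imply
  $F(0) > 0$, so their noise-free generator output is *not* their own curve
  at $t = 0$. The parameter-recovery oracles therefore use
  `zero_origin = FALSE` (recovery of truth from the family's own curve);
  realistic simulations keep the pin. This resolves an internal tension in
  the generator contract explicitly rather than silently.
* **between-feed jitter, lognormal sdlog 0.05 on m and r** — feeds within a
  category are different genotypes; a ~5% spread gives the Tukey and tree
  stages realistic within-category heterogeneity without moving category
  means.

What a green test establishes: that the pipeline recovers known truth under
its own assumed error model, at the published design's scale and noise
plausibility. What it does not establish: robustness to autocorrelated or
heteroscedastic noise, mechanistic fermentation behaviour, or the published
real-data cell values themselves (those enter only through the transcribed
reference summary, against which the package checks arithmetic identities,
not refits).

## Numerical choices

* Singular algebra at $t = 0$ (Burr III, Dagum, Frechet, Inverse
  exponential, Inverse paralogistic) evaluates as the right limit 0; these
  are valid CDFs with $F(0^+) = 0$.
* Below a bounded domain ($t < \mu$), cdf and pdf are 0 (lag semantics).
* Tukey with zero residual df or zero MSE degenerates to a single shared
  letter (no evidence of differences).
* The tree declines splits with SS reduction below $10^{-10}$; a constant
  response yields zero splits and an empty contribution vector.
* CSV outputs carry 6 significant digits (human tables); JSON reports keep
  full precision (machine reproducibility). One global seed fans out to
  stage and per-fit streams through a fixed integer recurrence kept below
  $2^{31}$.

## Limitations

Heteroscedastic or autocorrelated error models and mixed-effects pooling
across replicates are out of scope, as are ensemble trees and AIC-based
ranking (BIC is the selection metric throughout). The published real-data
tree (54 splits, training R² 0.76, 65.2%/34.8% contribution shares) is a
structural template only: without the raw curves those numbers are not
reproducible, and the package does not claim them.
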