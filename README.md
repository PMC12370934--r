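# gpkin

Model catalogue, fitting and selection for **in vitro gas production (GP)
kinetics**.

GP assays incubate ruminant feed with buffered rumen fluid and record
cumulative gas (mL per 200 mg dry matter) at fixed times — here the
Hohenheim Gas Test design with nine readings at 0, 2, 4, 6, 8, 12, 24, 48
and 72 h. Interpreting a GP curve means choosing a nonlinear model for it,
and the choice matters more than is usually acknowledged: different families
disagree far more about rate parameters than about the total yield. gpkin is
for animal-nutrition scientists and biostatisticians who want that choice
made systematically rather than by habit.

## The model and the statistics

Every curve is a scaled cumulative distribution function

```
GP(t) = m · F_u(t),        f(t) = GP'(t)
```

with asymptotic yield `m`, rate curve `f`, inflection time `t*` (mode of
`f`, gas `GP*`), and half-life `t0.5` (median; `GP0.5 = m/2`). The package
ships a fixed catalogue of **21 families** (Burr III/XII, Dagum,
Exponential 2p/3p, Exponentiated exponential, Frechet, Generalized
logistic, Gompertz, Gumbel, Cauchy and Half Cauchy, Logistic and Half
logistic, Inverse exponential, Log-logistic, Paralogistic and Inverse
paralogistic, Rayleigh 2p/3p, Weibull), each with closed-form `t*` and
`t0.5`.

Fitting is nonlinear least squares under an additive homoscedastic Gaussian
error model, with

```
BIC = k·ln(n) − 2·ln(L̂),     ln L̂ = −(n/2)(ln 2π + ln(RSS/n) + 1)
```

as the primary selection metric (`n = 9` readings, `k` parameters). The
selection layer ranks model × feed-category performance three ways: a Type
II factorial ANOVA on BIC, per-category Tukey HSD groupings with a compact
letter display, and a CART regression tree with per-predictor contribution
shares. The headline statistic is the **relative performance improvement**

```
RPI = 100 · (mean BIC lower set − mean BIC top set) / mean BIC all models
```

per feed category. Because the original raw curves are not publicly
deposited, the package includes a seeded synthetic generator that emulates
the assay design (849 profiles, six feed categories, 3–7 replicates per
feed), plus the published per-cell parameter/goodness-of-fit summary as a
plain-text reference table (`gp_reference_summary()`).

## Worked example

```r
library(gpkin)

prof <- simulate_profile("Burr XII", table2_presets("Burr XII", "Compound"),
                         noise_sd = 1.5, seed = 42, sample_id = "demo",
                         feed_category = "Compound")
fits <- fit_all(list(prof), models = c("Burr XII", "Log-logistic", "Cauchy"),
                options = gp_fit_options(seed = 1))
fits[, c("model", "m", "r", "t_half", "t_star", "r2", "rmse", "bic")]
#>          model    m     r t_half t_star    r2  rmse  bic
#> 1     Burr XII 73.6 0.159   6.63   2.62 0.999 0.896 32.3
#> 2 Log-logistic 73.3 0.151   6.62   2.61 0.999 0.897 30.2
#> 3       Cauchy 69.6 0.321   6.64   6.64 0.965 4.685 59.9
```

The flexible families agree on the kinetics (`m ≈ 73`, half-life ≈ 6.6 h,
inflection ≈ 2.6 h) and fit to ~0.9 mL; the rigid symmetric Cauchy is ~25
BIC points worse and misplaces the inflection at its centre. Note the BIC
penalty at work: Log-logistic (k = 3) edges Burr XII (k = 4) despite equal
RMSE. Full pipeline, small synthetic world:

```r
cfg <- gp_default_config("small")   # 6 categories × 2 feeds × 3 replicates
res <- run_pipeline(tempfile("run"), seed = 1, config = cfg,
                    models = c("Burr XII", "Log-logistic", "Dagum",
                               "Cauchy", "Gumbel"))
res$report$model_sets[, c("feed_category", "top_models", "lower_models", "rpi")]
#>       feed_category                  top_models  lower_models  rpi
#> 1          Compound Burr XII;Dagum;Log-logistic Cauchy;Gumbel 74.8
#> 2              Corn Dagum;Burr XII;Log-logistic Cauchy;Gumbel 63.8
#> 3 Processed protein Log-logistic;Burr XII;Dagum Cauchy;Gumbel 66.4
#> 4           Legumes Dagum;Burr XII;Log-logistic Cauchy;Gumbel 71.5
#> 5       Soft cereal              Dagum;Burr XII Cauchy;Gumbel 62.9
#> 6            Others Log-logistic;Burr XII;Dagum Cauchy;Gumbel 56.2
```

Per category: Tukey top/lower model sets and the RPI percentage — e.g. in
the Compound block the top set outperforms the lower set by ~75% of the
category's average BIC. `run_pipeline()` also writes `profiles.csv`,
`fits.csv`, `report.json` (ANOVA + Tukey + tree + model sets),
`leaf_report.csv` and a reproducibility manifest.

A command-line wrapper covers the same stages
(`models` / `simulate` / `fit` / `select` / `run` / `report`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli/gpkin", package = "gpkin"))') \
    run --preset small --seed 1 --out-dir out
```

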