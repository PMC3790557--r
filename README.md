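# phenogamm

Generalized additive mixed models (GAMMs) for monthly presence–absence
phenology panels: long-term records of whether each marked plant in a forest
plot carries fruit. Such panels mix three signals that field ecologists need
to separate — a regular within-year cycle, slow across-year change, and
episodic anomalies such as a community-wide "good year". phenogamm fits
binomial logit additive models that decompose the log-odds of fruiting into

```
logit P(y_tk = 1) = b0 + b1 * y_{t-1,k} + s1(t) + s2(calendar month) + b_k
```

where `s1` is a penalized natural cubic regression spline over the month
index (the interannual trend), `s2` a cyclic cubic regression spline over
the calendar month (seasonality, exactly periodic over 12 months), `b1` a
lag-1 persistence coefficient, and `b_k ~ N(0, sigma^2)` per-plant random
intercepts. The penalized-spline engine is implemented from scratch in the
package: quadratic roughness penalties (integrated squared second
derivative, closed form), penalized IRLS fitting, joint maximum-likelihood
selection of all smoothing parameters and the random-effect variance via a
Laplace-approximate marginal likelihood, Bayesian credible bands, Wald
chi-square tests of smooth terms, and likelihood ratio tests with a
structural degrees-of-freedom rule for nested model structures (M1:
smooth trend + seasonality, M2: linear trend + seasonality, M3: smooth
trend, M4: seasonality, M5: null).

Around that core the package provides the full analysis pipeline:

* **`fit_hmm()` / `impute_panel()`** — per-plant two-state Bernoulli hidden
  Markov models (Baum–Welch, scaled forward–backward) to impute missing
  months before the lagged model is fitted.
* **`two_step_select()`** — likelihood-ratio screening of M1–M5 followed by
  zero-function inspection of the credible bands, giving each species a
  final structure.
* **`classify_trend()` / `sort_species_by_trend()`** — qualitative monthly
  trend labels (positive / negative / none) per species from the final
  model's bands.
* **`run_sim_experiment()`** — the simulation study of P-value reliability
  and credible-interval coverage for smooth terms (20 plants, 120 months,
  reconstructed generating functions).
* **`generate_panel()` / `default_bwindi_profiles()`** — a synthetic
  multi-species panel generator (33 species / 249 plants / 95 months / 6%
  missingness) so the whole pipeline runs without any field data.
* **`run_pipeline()`** — impute, select, classify, and summarize a panel
  end to end, with JSON/CSV artifacts and a run manifest.

## Worked example

Simulate one species (8 plants, 95 months) with seasonality, a positive
fruiting anomaly around months 45–70, plant-level heterogeneity and
serial persistence; impute; select a model; classify the trend:

```r
library(phenogamm)

profiles <- list(
  species_profile("Maesa_lanceolata", 8,
                  trend_type = "nonlinear",
                  trend_params = list(center = 57, half_width = 8,
                                      amplitude = 1.8),
                  seasonal_amplitude = 1.2, peak_month = 2,
                  re_sd = 0.5, lag_coef = 0.8, baseline_logit = -0.4))
panel <- generate_panel(profiles, n_months = 95, missing_rate = 0.06,
                        seed = 42)
panel <- impute_panel(panel)

decision <- two_step_select(panel, alpha = 0.05)
decision
#> Two-step model selection: chosen M1 (step 1: M1)
#>   M1 vs M5: chi-sq = 69.47, df = 3, p = 5.554e-15
#>   M1 vs M2: chi-sq = 18.48, df = 1, p = 1.715e-05
#>   M1 vs M3: chi-sq = 54.82, df = 1, p = 1.321e-13
#>   M1 vs M4: chi-sq = 23.68, df = 2, p = 7.216e-06
#>   trend smooth zero-exclusion fraction: 0.53
#>   seasonal smooth zero-exclusion fraction: 0.75

summary(decision$fit)
#> Binomial additive model (logit link)
#> n = 752, deviance = 799.89, marginal logLik = -423.30
#> Smooth terms (edf):
#>   s(month_index)         edf =  4.67  lambda = 3109
#>   s(calendar_month)      edf =  3.67  lambda = 5.234
#> Random intercepts re(plant_id): sd = 0.531
#>
#> Approximate significance of smooth terms:
#>   s(month_index)         edf =  4.67  chi-sq =    30.81  rank = 5  p = 1.022e-05
#>   s(calendar_month)      edf =  3.67  chi-sq =    59.26  rank = 4  p = 4.156e-12

table(classify_trend(decision, months = 2:95))
#> negative     none positive
#>       24       44       26
```

The two-step procedure recovers the generating structure M1: every reduced
model is rejected (note df = 3 against the null and df = 1 against the
linear-trend model — the structural rule), both smooths are individually
significant, the estimated plant heterogeneity (0.53) matches the
generating value 0.5, and the positive trend labels span months 47–72,
bracketing the simulated anomaly. Months labeled negative are the fitted
trend's compensating trough — with a sum-to-zero trend, a strong positive
episode implies below-average odds elsewhere.

`plot(decision$fit)` draws both smooths with 95% credible bands;
`run_pipeline(list(seed = 1))` runs the same analysis over the full
33-species synthetic panel and prints a five-category table of selected
structures.

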