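# mipsATE

Multiply robust estimation of the average treatment effect (ATE) from
observational data via **multi-index propensity scores**.

## The problem

With observational data, the ATE Δ = E(Y¹) − E(Y⁰) is usually estimated
by inverse probability weighting (IPW, needs a correct propensity-score
model), outcome regression (OR, needs a correct outcome model) or
augmented IPW (AIPW, needs one of its single model pair correct). An
analyst who entertains K candidate propensity models and L candidate
outcome models has no principled way to pick the right one — and
classical estimators fail if the chosen model is wrong.

## The method

Fit *all* K + L single-index candidate models, keep only their fitted
linear indices α̂₁ᵏᵀX and β̂₁ˡᵀX, and regress treatment nonparametrically
on the stacked d = K + L dimensional index:

    π_MiPS(S) = E(A | α̂₁¹ᵀX, …, α̂₁ᴷᵀX, β̂₁¹ᵀX, …, β̂₁ᴸᵀX).

Plugging this *multi-index propensity score* into normalized (Hajek)
inverse probability weights gives an ATE estimator that is consistent
whenever **any one** of the K + L candidate models is correctly
specified. Two smoothers estimate E(A | S):

* `Ker.MiPS` — multivariate Nadaraya–Watson kernel smoother with product
  Gaussian kernel and Scott bandwidths (degrades quickly as d grows);
* `ANN.MiPS` — a small feed-forward neural network (d → 4 → 4 → 1, tanh
  hidden layers, sigmoid output) trained with momentum gradient descent;
  the sigmoid output keeps every score strictly inside (0, 1) and the
  network handles larger d gracefully.

The package also provides the classical IPW/OR/AIPW estimators for
comparison, full-pipeline bootstrap standard errors with Wald confidence
intervals, a synthetic data-generating process with known true effect
Δ = −0.4, and a Monte Carlo study harness. See the vignette
(`vignettes/multi-index-propensity-scores.Rmd`) for the methodology in
detail.

## A worked example

Generate a benchmark dataset (10 standard-normal covariates, logistic
treatment, linear outcome, true ATE −0.4), then estimate the ATE with the
network-smoothed multi-index score built from all four benchmark
candidate models (bitmask `1111` = PS1, PS2, OR1, OR2 — one correct and
one misspecified model of each type):

```r
library(mipsATE)

d <- gen_dataset(dgp_config(n = 1000, alpha0 = 0, seed = 1))
d
#> <observed_data> n = 1000, p = 10, treated = 509 (50.9%)

est <- estimate_with_ci(d, method = "ANN.MiPS", bitmask = "1111",
                        B = 100, seed = 1)
round(c(estimate = est$estimate, se = est$se, est$ci), 4)
#> estimate       se                   
#>  -0.3435   0.0722  -0.4850  -0.2020
```

The interval covers the true value −0.4. A small Monte Carlo study shows
the multiple-robustness pattern — the correctly specified IPW and the
multi-index estimator are nearly unbiased, while IPW under the
misspecified candidate (squared covariates, bitmask `0100`) is badly
biased:

```r
cfg <- study_config(
  dgp = dgp_config(n = 1000, alpha0 = 0),
  replications = 50,
  estimators = list(
    study_estimator("IPW", "1000"),
    study_estimator("IPW", "0100"),
    study_estimator("ANN.MiPS", "1111")
  ),
  seed = 7
)
run_study(cfg)
#> Monte Carlo study: 50 replications, true ATE -0.4
#>
#>      estimator bias_pct  rmse mc_se bs_se ci_cov n_failed
#>       IPW-1000   -0.766 0.087 0.088    NA     NA        0
#>       IPW-0100   42.855 0.203 0.109    NA     NA        0
#>  ANN.MiPS-1111    0.039 0.061 0.062    NA     NA        0
```

A command-line interface for dataset simulation, single estimates and
full studies (YAML-configured) lives at `inst/cli/mips.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "mips.R", package = "mipsATE"))')" \
  simulate --n 1000 --alpha0 0 --seed 1 --out data.csv
```

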