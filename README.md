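# persistLSD

Persistence modelling for declining populations: latent selection
differences with imperfect detection.

## The problem

When a species is declining, the sites it occupied historically split into
two classes — those where the population **persisted** and those where it
was **extirpated**. Contrasting the attributes of the two classes
identifies correlates of local extinction. `persistLSD` implements this
contrast for repeat-survey monitoring data (the motivating design: 43
historically occupied lakes surveyed up to three times in one season for a
colonial waterbird), for ecologists and conservation analysts who have a
detection-history table and site covariates and want a ranked, checked set
of persistence models.

Two models sit at the core:

* **Latent selection difference (LSD).** Logistic regression of the
  persisted/extirpated labels on site covariates, summarized by the
  exponential score *w*(**x**) = exp(β₁x₁ + … + βₖxₖ). Both site classes
  share one availability distribution, so only *relative* persistence is
  identified; the intercept is excluded from the score.
* **Persistence with imperfect detection.** The single-season occupancy
  likelihood over detection histories *y*ᵢⱼ ∈ {0, 1, missing}:

  *L*ᵢ = ψᵢ ∏ⱼ pᵢⱼ^yᵢⱼ (1 − pᵢⱼ)^(1−yᵢⱼ) + (1 − ψᵢ) I[no detection],

  with ψᵢ = logit⁻¹(**x**ᵢ′**β**) and pᵢⱼ = logit⁻¹(**v**ᵢⱼ′**α**),
  maximized by BFGS with observed-information standard errors.

Around them: covariate preparation (log transforms, |r| > 0.65
collinearity screening with univariate-AICc tie-breaking), AICc ranking
with Akaike weights, a-priori candidate sets, MacKenzie–Bailey-style
parametric-bootstrap goodness of fit (ĉ), a detection-history simulator,
and a pipeline/CLI chaining all stages.

## Worked example

```r
library(persistLSD)

dat <- simulate_dataset(grebe_sim_config(seed = 1))  # 43 lakes, 3 visits
dat$histories
#> Detection history: 43 sites x 3 occasions
#>   surveyed cells: 104 of 129; sites with >=1 detection: 21

naive_estimate(dat$histories)          # uncorrected persistence: 21/43 = 49%

fit <- fit_occupancy(dat$histories, dat$bundle, model_spec("Develop", "Rush"))
fit
#> Occupancy/persistence fit: psi(Develop) p(Rush)
#>   n = 43 sites, K = 4 params, logL = -58.7329 (-2LL = 117.4659)
#>                   estimate        se
#> psi.(Intercept)  0.2042754 0.5614826
#> psi.Develop     -0.7272745 3.2531423
#> p.(Intercept)    1.1590960 0.6560887
#> p.Rush          -2.0561620 2.2185231

gof_test(fit, dat$histories, dat$bundle, nboot = 200, seed = 1)
#> Parametric-bootstrap GoF (200 replicates, 0 failed):
#>   test statistic = 8.102, c-hat = 0.557, P = 0.950
```

The fit reports the persistence (ψ) and detection (p) coefficients on the
logit scale with their standard errors: here shoreline bulrush (`Rush`)
reduces per-visit detectability (p.Rush < 0), and detection-corrected
persistence (`mean(predict_psi(fit, dat$bundle))` ≈ 0.53) exceeds the
naive 49% because some occupied lakes were simply missed. The
GoF p-value of 0.95 and ĉ well below ~1.2 indicate no lack of fit or
overdispersion at this sample size. A single 43-site ĉ is a noisy draw —
its calibration is checked on averages over repeated runs (see the
vignette).

`run_full_analysis()` chains the published workflow: rank 13 a-priori LSD
structures, carry the top ≤ 4 into the detection-corrected likelihood
crossed with `p(.)/p(Rush)/p(Date)/p(Rush+Date)`, re-rank, run the GoF
bootstrap on the global detection model, and correlate the top model's ψ̂
against an external occupancy score. The same pipeline is scriptable from
the shell via `inst/cli/persistlsd`
(`simulate | lsd | fit | rank | gof | compare | run`).

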