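# echinofert

Statistical tools for multi-stressor reproduction experiments on
broadcast-spawning echinoderms (sand dollars, sea urchins), where eggs and
sperm meet in the water column and both warming and acidification can
impair fertilization. The package provides the full analysis chain for the
two standard assay designs in this field — a single-factor thermal series
and a temperature × pH factorial — over seeded synthetic data, so every
method is testable end to end without raw field data.

## What it computes

* **Synthetic assays** with the structure of the real experiments:
  binomial fertilization counts (pairs × technical replicates of 50 eggs)
  whose success probability follows a thermal performance curve with
  pair-level heterogeneity and additive pH effects on the logit, per-sperm
  velocity samples, and circular 2-D sperm tracks sampled at 60 Hz.
* **Sperm kinematics**: curvilinear velocity (VCL = chord-sum path length
  ÷ elapsed time, µm/s) and motility (fraction of tracks with VCL above a
  noise-floor threshold, default 5 µm/s).
* **Thermal performance curves (TPCs)**: bounded multistart nonlinear
  least squares over a 10-model registry (quadratic, gaussian, modified
  gaussian, Brière-II, Sharpe–Schoolfield, Ratkowsky, Weibull, Lactin-II,
  Rezende, Flinn), ranked by small-sample AICc; derived parameters
  r_max, T_opt, and thermal breadth T_br (width of the region where the
  rate exceeds 80% of the maximum) with residual-bootstrap percentile
  confidence intervals.
* **Fertilization kinetics**: the collision model
  φ = 1 − exp(−(βS₀/β₀E₀)(1 − e^(−β₀E₀t))), with contact rate constant
  β₀ = υσ₀ computed from measured sperm velocity υ and egg cross-section
  σ₀; one-dimensional least-squares fitting of the β/β₀ ratio; and
  per-condition comparison of modelled vs measured fertilization.
* **ART factorial ANOVA**: the aligned rank transform for nonparametric
  two-factor designs (align by cell-mean algebra, midrank, standard
  two-way ANOVA per effect), with partial η², Bonferroni pairwise
  contrasts using the model error term, Cohen's d, and Spearman rank
  correlations.

## Worked example

Simulate the 12-temperature sand-dollar design (three male–female pairs
per temperature, three 50-egg technical replicates each), aggregate to
biological replicates, rank candidate TPC models, and bootstrap the
derived parameters:

```r
library(echinofert)

des  <- design_spec()                       # 12 temperatures x 3 pairs x 3 reps
sim  <- generate_single_factor_assay(des, truth_spec(seed = 2024))
fert <- aggregate_fertilization(sim$assay)  # technical -> biological replicates

ds <- tpc_dataset(fert$temperature_c, fert$fertilization_prop,
                  fert$pair_id, trait_name = "fertilization")
rk <- rank_tpc_models(ds, c("quadratic", "gaussian", "modgaussian"), seed = 1)
print(rk)
#> TPC model ranking (ascending AICc):
#>        model k       rss      aicc       bic delta_aicc
#>     gaussian 4 0.1535361 -85.01030 -79.96654   0.000000
#>  modgaussian 5 0.1498101 -83.18504 -77.26745   1.825254
#>    quadratic 4 0.6240697 -34.52654 -29.48279  50.483753

boot <- bootstrap_tpc(rk[[1]], n_boot = 1000, seed = 2)
print(boot)
#> Residual bootstrap, 1000 replicates (0 failed), 95% CIs:
#>  quantity   estimate       low       high
#>     r_max  0.9505446  0.912063  0.9926169
#>     t_opt 17.7439659 17.357837 18.1408299
#>      t_br  9.9107278  9.263520 10.6098542
```

The gaussian wins decisively (ΔAICc > 50 over the quadratic; `k` counts
curve parameters plus the residual-variance parameter). The fitted
thermal optimum is 17.7 °C (95% CI 17.4–18.1) against a generating truth
of 17.6 °C, with a maximum fertilization proportion of 0.95 and an 80%
thermal breadth of 9.9 °C.

The numbered scripts under `analysis/` run the whole workflow — simulate
both experiments, summarise kinematics, fit TPCs for fertilization /
velocity / motility in both species, fit the kinetics ratio and compare
modelled with measured fertilization, and run the ART ANOVA on the
factorial — writing tables under `results/`. A config-driven equivalent
is `run_pipeline(read_run_config(system.file("extdata",
"demo_config.yaml", package = "echinofert")))`, which produces
byte-identical outputs on re-runs of the same config.

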