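---
title: "Methods: thermal performance, sperm kinematics, and fertilization kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal performance, sperm kinematics, and fertilization kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echinofert)
```

# Scope

`echinofert` implements the statistical machinery for multi-stressor
reproduction experiments on broadcast-spawning echinoderms: a seeded
synthetic-data generator with the structure of the two canonical assay
designs, sperm curvilinear-velocity and motility summaries, thermal
performance curve (TPC) fitting with AICc model selection and
residual-bootstrap uncertainty, a collision-kinetics model of
fertilization, and aligned-rank-transform (ART) factorial ANOVA. The
numbered scripts under `analysis/` chain these stages into a complete,
reproducible workflow over simulated data; every computation lives in the
package and is unit-tested.

# The synthetic-data generator

The generator exists so that every downstream stage is exercised on data
with the right *structure*, without any external download. It emulates
two designs:

* **Single-factor thermal series.** Twelve temperatures (8–38 °C, the
  sand-dollar layout) or seven (8–28 °C, the red-urchin layout), three
  independent male–female pairs per temperature (biological replicates),
  three technical replicates of 50 eggs each, so 150 eggs per pair.
* **Temperature × pH factorial.** Three temperatures (8, 16, 24 °C)
  crossed with three pH levels (7.1, 7.5, 7.9 — approximately 1825, 700
  and 425 µatm pCO₂); each pair is nested in one temperature but tested
  across all three pH levels, three pairs per temperature.

Fertilization counts are binomial: the success probability is a true
fertilization TPC evaluated at the treatment temperature, shifted on the
logit scale by (a) a pair-level random effect, Normal(0, `pair_sd_logit`),
and (b) an additive per-level pH offset. The logit-normal pair effect is
the simplest exchangeable heterogeneity model that keeps probabilities in
(0, 1); real experiments report biological replication but no variance
structure, so this choice is ours, and its default SD (0.4, roughly ±10
percentage points around p ≈ 0.9) is labelled synthetic. pH enters as
discrete per-level offsets rather than a continuous slope, mirroring the
three-level treatment design.

Individual sperm velocities are Normal around the velocity TPC with a
stated coefficient of variation (default 0.2), truncated at 0; motility
is Bernoulli with probability given by a motility TPC; immotile cells
receive a jitter velocity below the tracking noise floor (uniform on
[0, 2] µm/s). Default truth curves are gaussian with optima near
14–18 °C and maxima of 0.95 (fertilization probability), 300 µm/s
(velocity) and 0.8 (motile fraction) — qualitative shapes typical for
temperate echinoderms, explicitly synthetic, not estimates.

Simulated sperm tracks are circles (the stereotyped swimming pattern of
echinoid sperm near surfaces) of radius 50 µm by default, sampled at
60 Hz for 10 s (600 points). The angular step per frame is
`2 asin(chord / 2r)` with `chord = speed / frame_rate`, which makes the
chord-sum (curvilinear) speed equal the requested speed *exactly*;
requests whose chord cannot be placed on the circle are rejected as
undersampled. The generator does not emulate Brownian wobble, cell
collisions, drift, or out-of-focus loss — so passing kinematics tests
demonstrate correctness of the VCL computation, not robustness to real
tracking artefacts.

What the generator deliberately does not model: seawater carbonate
chemistry (pH levels are labels), egg-density effects within a dish,
time-varying temperature, and any sperm–egg interaction beyond the
binomial draw. Conclusions from simulated runs are about the methods,
not about animals.

# Sperm kinematics

Curvilinear velocity (VCL) is the total point-to-point path length
divided by elapsed time, `(n − 1) / frame_rate`. No smoothing is applied
before chord summation; an unsmoothed VCL is an upper bound among the
CASA velocity measures (it always dominates straight-line velocity, a
property the tests enforce).

Motility is the fraction of tracks whose VCL *strictly* exceeds a
threshold. A literal "moving at all" rule is unusable under measurement
noise — every digitised cell shows some apparent displacement — so the
default threshold is 5 µm/s, a typical digitising noise floor at 60 Hz;
it is configurable everywhere it appears. The sample mean VCL averages
motile tracks only (immotile cells would drag the mean toward the noise
floor; continuously swimming cells are the biological quantity);
`motile_only = FALSE` includes all tracks for sensitivity analysis.

# Thermal performance curves

## Candidate registry and fitting

Ten candidate forms are registered: quadratic, gaussian, modified
gaussian (free exponent), Brière-II, Sharpe–Schoolfield with
high-temperature inactivation, Ratkowsky, Weibull, Lactin-II, Rezende
and Flinn. The registry is extensible; the three forms that matter most
in practice for these traits (quadratic, gaussian, modified gaussian)
are the default pipeline set and the most heavily tested.

Fitting is bounded multistart nonlinear least squares: box constraints
are data-driven (location parameters track the observed temperature
range, scale parameters the rate range), and the default 10 starts are
the model's data-driven heuristic start (optimum near the argmax of
observed rates, height near the maximum rate), jittered copies, and
uniform draws within bounds, all seeded. Each start is polished with
L-BFGS-B, falling back to Nelder–Mead on a bound-clamped objective when
the gradient run fails; the best converged start wins, and the
convergence flag is honest — models where every start fails are excluded
from ranking with a logged reason, never silently dropped.

## Information criteria

Models are ranked by small-sample corrected AICc under the Gaussian
likelihood, `logLik = −n/2 (log 2π + log(rss/n) + 1)`. **Convention:**
`k` counts the curve parameters *plus one* residual-variance parameter.
Published AICc values differ by exactly this convention, so it is stated
prominently; BIC is reported alongside. Models with `n − k − 1 ≤ 0` have
no defined AICc and are excluded with an explicit status. A numerically
zero RSS (noiseless data) has no finite Gaussian likelihood; the RSS is
floored at `1e-12 · max(1, Σy²)` for the criteria only, flagged in the
fit status. Ties in AICc break by fewer parameters, then model name, so
rankings are invariant to the order candidates are supplied.

## Derived parameters

`r_max` and `T_opt` are located on a dense grid (default 0.01 °C)
refined by golden-section search in the bracketing cells. Thermal
breadth `T_br` is the total width of the region where the fitted rate is
at least 80% (configurable) of `r_max`, with region boundaries located
by linear interpolation between grid points, clipped to the assessed
range. Negative fitted rates (quadratic tails) are clamped to zero for
derived parameters only — never during fitting, where clamping would
bias the least-squares surface. A non-contiguous super-threshold region
reports its total measure with `contiguous = FALSE` (unimodal fits give
one interval); a region touching the grid edge is flagged
`boundary_censored` and no extrapolation beyond the data range is
attempted.

## Bootstrap

Uncertainty is by residual bootstrap, matching how TPC confidence bands
are usually constructed for these traits: centred residuals are resampled
with replacement, added to fitted values, the model is refitted starting
from the original estimates, and the derived parameters recomputed;
percentile intervals are reported at the requested level. Refit failures
are skipped, counted, and reported as a failure rate; above 50% the
intervals are flagged unreliable. The residual bootstrap assumes
exchangeable homoscedastic residuals — with binomial assay noise this is
an approximation whose adequacy the coverage test quantifies.

# Fertilization kinetics

The collision-kinetics model predicts the proportion of fertilized eggs

$$\varphi = 1 - \exp\!\Big(-\frac{\beta S_0}{\beta_0 E_0}\big(1 - e^{-\beta_0 E_0 t}\big)\Big)$$

with sperm and egg concentrations \(S_0, E_0\) (counts/µl), exposure
time \(t\) (s), fertilization rate constant \(\beta\) and egg–sperm
contact rate constant \(\beta_0\) (mm³/s), the latter computable from
swimming as \(\beta_0 = \upsilon \sigma_0\) (velocity µm/s × egg
cross-section µm², converted exactly by 1 mm³ = 10⁹ µm³). All internal
units are mm³ and seconds; per-µl concentrations are numerically per-mm³
(1 µl = 1 mm³ identically). The implementation uses `expm1` so the small-
and large-exposure limits hold to machine precision, and the model's
core monotonicity — faster sperm can never reduce predicted
fertilization at fixed \(\beta/\beta_0\) — is enforced by
property tests over randomized parameter sweeps.

The ratio \(\beta/\beta_0\) is fitted by one-dimensional least squares
on (0, upper]; predicted \(\varphi\) is monotone in the ratio, so
bounded golden-section minimisation suffices and no multistart is
needed. A fit where every observation is exactly 0 or 1 is rejected as
non-identifiable. Both a global fit and per-condition fits are possible
(the workflow fits globally; per-condition is one `split` away) because
which the field uses varies by study.

\(E_0\), \(\sigma_0\) and exposure protocols are required inputs with
documented illustrative defaults (egg diameter 130 µm for
sand-dollar-sized eggs, \(E_0\) = 0.02 eggs/µl, t = 900 s, and
\(S_0 \approx 0.455\) sperm/µl from the worked dilution helper: 10⁵
sperm/ml stock, 50 µl into an 11 ml dish). These defaults are marked
non-authoritative throughout; the prediction tables carry every
parameter used so each number is reproducible from the file alone. The
model-vs-measured comparison reports predicted minus measured
fertilization per condition plus the rank correlation between measured
fertilization and velocity; unmatched conditions appear as explicit
`NA` rows.

# ART factorial ANOVA

Where the general linear model's assumptions fail, the factorial
analysis uses the aligned rank transform: for each effect (two main
effects and the interaction) the responses are *aligned* — stripped of
all other effects by cell-mean algebra — then converted to midranks over
the whole sample, and a standard balanced two-way fixed-effects ANOVA is
run on the ranks, of which only the target effect's F is interpreted.
Aligned responses sum to zero by construction (a diagnostic the package
reports), and the "stripped" F statistics of non-target effects on each
aligned-ranked set are reported as alignment diagnostics.

Replicate-level means enter the ANOVA directly: technical replicates are
averaged per pair first, and pairs are treated as exchangeable within
cells rather than as a blocking factor. This reproduces the denominator
degrees of freedom (e.g. 18 for a 3 × 3 design with 3 pairs per cell)
that this style of analysis reports. Midranks handle ties, the standard
choice in the ART literature.

Pairwise posthoc contrasts use the full model's error mean square and
residual degrees of freedom on the aligned-ranked data — a plain
two-sample t test would understate the error after alignment (alignment
subtracts estimated cell effects, deflating apparent within-group
variance) and inflate the familywise error, which a calibration test in
the suite demonstrates is avoided. Bonferroni adjustment is
`min(1, m·p)` over the m level pairs; Cohen's d with pooled SD is
reported on the raw response scale, classified on the conventional
small/medium/large/very large/huge thresholds (configurable).

Spearman correlations are Pearson correlations of midranks with the
large-sample t approximation for the p value; for the n ≈ 30–40 condition
tables this analysis produces, the approximation error is far below any
decision threshold.

# Numerical and design choices

* All randomness is seeded; seeded evaluation restores the caller's RNG
  state, and multi-stage runs derive per-stage child seeds
  deterministically from one master seed (kept below 2³¹).
* The pipeline writes no timestamps into outputs, so identical configs
  produce byte-identical output trees — the determinism contract is
  tested at the byte level.
* Degenerate inputs have defined behaviour rather than surprises:
  zero-exposure and zero-sperm limits return 0, all-immotile samples
  report `mean_vcl = 0` with an explicit flag, constant-rate TPC data
  converge to the flat limit, saturated kinetics observations and
  constant rank-correlation inputs are rejected with messages.
* Problem sizes in the test suite are chosen to keep the full run in a
  few minutes while leaving Monte-Carlo error well inside the asserted
  bands: 100 simulations for parameter-recovery and model-selection
  checks, 200 simulations × 200 bootstrap draws for interval coverage,
  1000 null simulations for ART type-I calibration. Production analyses
  should use larger bootstrap sizes (the `analysis/` scripts use 1000;
  several thousand is typical for publication).

# Known limitations

* The TPC registry's functional forms are fixed per model; users needing
  exotic forms register their own `tpc_model_spec`.
* The residual bootstrap ignores heteroscedasticity of binomial
  proportions near 0/1; a parametric (binomial) bootstrap would be the
  next refinement.
* ART here is two-factor, balanced, fixed-effects; mixed-effects ART
  (pair as a random blocking factor) is not implemented.
* The kinetics model omits polyspermy, sperm aging, chemoattraction and
  egg-receptor dynamics; it is exactly the tool needed to ask whether
  swimming speed *alone* explains fertilization patterns, and nothing
  more.
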