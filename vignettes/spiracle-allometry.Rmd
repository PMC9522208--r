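---
title: "Spiracle allometry and gas-exchange capacity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiracle allometry and gas-exchange capacity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spirascale)
```

## The scientific problem

Insects breathe through spiracles: small, gated openings that connect outside
air to an internal network of tracheal tubes. Because oxygen demand grows
roughly with body volume while exchange surfaces grow with area, how spiracle
dimensions scale with body mass determines whether a large insect can still
breathe by diffusion alone, or must ventilate actively. `spirascale`
implements the full analysis chain for this question in scarab beetles:
per-spiracle morphometrics, biophysical conductances, the oxygen
partial-pressure gradient required to run metabolism on diffusion, and
allometric regressions with bootstrap, Bayesian and phylogenetic inference.

## Morphometrics

Each of the eight spiracles per side (mesothoracic S, metathoracic T,
abdominal A1–A6) is measured by two orthogonal opening diameters and a depth.
The opening is modelled as an ellipse with the two diameters as its axes:

$$A = \pi \, \frac{d_t}{2} \, \frac{d_s}{2}.$$

A reading of the measurement convention in which the diameters are the
*semi*-axes (area $\pi d_t d_s$, four times larger) is exposed via
`literal_semi_axes = TRUE` for sensitivity checks only; it breaks the circular
limit and is not the default. Raw measurements are stored in mm (the scale of
micro-CT voxels); all biophysics is done in cm, with conversions centralized
in the morphometry layer. Derived per-spiracle metrics are depth (cm), area
(cm²), the diffusive index area/depth (cm) and the advective index
area²/depth (cm³). Whole-animal totals sum all eight spiracles and double the
result (measurements cover one of two symmetric sides). Missing spiracles are
a hard error in totals — imputation by the conspecific mean for that label is
available behind `impute = TRUE`, but per-spiracle regressions simply drop
absent measurements.

## Biophysics

Diffusive conductance follows Fick's law,
$G_\mathrm{diff} = (A/L)\,D\,\beta$, with $D = 0.178$ cm² s⁻¹ (O₂ diffusivity
in air) and $\beta = 404$ nmol cm⁻³ kPa⁻¹ (O₂ capacitance coefficient), so
Krogh's constant is $K = D\beta$. Advective conductance follows Poiseuille's
law, $G_\mathrm{adv} = A^2 / (8 \mu L)$ with $\mu = 1.86\times10^{-8}$ kPa s,
reported in m³ s⁻¹ kPa⁻¹. All constants are frozen at 25 °C — no temperature
correction is applied — and can be overridden through
`physical_constants()`.

Resting metabolic rate uses the standard insect allometry
$\log_{10}(\mathrm{MR}, \mu W) = 3.2 + 0.75\,\log_{10}(m, g)$, converted to
oxygen consumption through the energy equivalent of oxygen at RQ 0.85
(20.7 µJ per nL O₂) and the molar gas volume at 25 °C (24.5 nL per nmol).
Note that quoting these factors in bulk units ("kJ/L", "mol/L") is
dimensionally treacherous; the implementation follows the per-nL/per-nmol
chain exactly. The gradient required to supply a metabolic state by diffusion
is then

$$\Delta P_{O_2} = \frac{10^{\log_{10}AS + 3.2 + EXP\,\log_{10} m} /
(20.7 \times 24.5)}{G_\mathrm{diff,total}},$$

where $AS$ is the aerobic scope (1 at rest; 90, the median of reported
maximal beetle scopes of 80/90/110, for flight) and $EXP$ the metabolic
scaling exponent (0.75 resting; 0.67 and 1.19 bracket the flight literature
for large and small insects). At 1 g the scope factors out exactly — the
flight/rest ratio equals $AS$ and $EXP$ is inert — which the tests use as an
algebraic anchor. Gradients above the 21 kPa atmospheric ceiling are flagged
as infeasible for diffusion.

`required_dpo2()` can be evaluated per specimen or along a fitted
total-conductance regression line; the curve functions use the
regression-line mode, which is the natural choice for smooth curve endpoints
(per-specimen evaluation is available through `run_capacities()`).

## Scaling statistics

Every metric is regressed on body mass on log10–log10 axes by OLS, the
regression unit being the individual specimen. Uncertainty comes from a
nonparametric case-resampling bootstrap (default $B = 10{,}000$): resampled
(mass, value) pairs, OLS refit per replicate, percentile intervals using
linear interpolation between order statistics (`quantile` type 7, fixed for
bit-reproducibility under a stored seed). Resamples in which all masses
coincide leave the slope undefined; they are redrawn and counted. Two-sided
bootstrap p-values against a reference slope (isometry: 0.67 for areas, 0.33
for depths and area/depth, 1 for area²/depth) are
$p = \min(1, 2\min(\hat F(b_0), 1 - \hat F(b_0)))$.

The relative-variability statistic — residual sd divided by $10^{\text{intercept}}$,
the predicted trait value of a 1 g animal — makes spread comparable across
spiracles of very different absolute size; bootstrap and posterior variants
summarise it by median and interval (bootstrap at 2.5–97.5%, posterior HPD at
94%, the "3rd–97th" convention of comparable figures; both configurable).

The Bayesian regression is a normal likelihood with a linear mean, sampled
with JAGS. Priors are weakly informative and overridable: slope and intercept
Normal(0, 5), residual sd HalfNormal(1), all on the log10 scale — diffuse
relative to any plausible allometric exponent. Convergence is monitored by
effective sample size and flagged in the result, never silently. The
prior-only case ($n = 0$) is sampled directly from the priors in R, since
JAGS rejects zero-length data loops.

A known property worth stating plainly: at $n = 17$ the plain percentile
bootstrap interval undercovers. In the package's own calibration simulations
(500 replicates, log-uniform masses over 0.097–18 g, log10 noise sd 0.1) the
95% interval covers the true slope ~92–93% of the time, while the classical
t-interval covers ~95% and the Bayesian 95% HPD ~94–98%. This is the
well-documented small-sample behaviour of percentile intervals, not an
implementation artefact (an independent brute-force bootstrap reproduces the
number exactly); users wanting nominal small-sample coverage should lean on
the Bayesian interval.

## Phylogenetic comparative layer

Trees are read from newick via `ape`; unit branch lengths can be imposed when
divergence times are unknown. The specimen-level covariance sets entry
$(i,j)$ to the shared branch length of the two specimens' species, times
Pagel's $\lambda$ off the diagonal; conspecific specimens share the full tip
depth, and a small diagonal jitter (default $10^{-6}\times$ tip depth) keeps
the matrix invertible. `pgls_fit()` computes the GLS estimate
$(X^\top V^{-1}X)^{-1}X^\top V^{-1}y$ by Cholesky whitening; with identity
covariance it equals OLS to numerical precision, and tests verify it against
an independent whitening oracle.

`lambda_profile()` evaluates the maximized log-likelihood over a $\lambda$
grid and summarises flatness as max − min. The identifiability threshold is
declared a priori at 1.92 log-likelihood units (half the 95% $\chi^2_1$
quantile): below it, no $\lambda$ can be rejected against another at the 5%
level. Two modelling subtleties matter with replicate conspecific specimens:

* At $\lambda = 1$ the Pagel matrix is singular (conspecifics forced
  identical) and invertible only through the jitter, so the likelihood there
  measures the regularization, not the data. Such grid points are flagged
  `jitter_dominated` and excluded from the flatness summary.
* Under the single-variance GLS model the conspecific replicates alone can
  reject large $\lambda$, overstating identifiability. The
  `error_term = "profiled"` variant uses
  $\sigma^2[(1-w)V(\lambda)/\bar{c} + wI]$ with the independent-error weight
  $w$ profiled out per grid point — the shared-ancestry-plus-residual
  structure appropriate to individual-level data, under which $\lambda$ is
  informed only by between-species contrasts. At the study design
  (17 specimens, 10 species) this variant is nonidentifiable in the large
  majority of simulation runs, while remaining clearly identifiable for
  strong signal at larger species counts.

Consistent with that diagnostic, the pipeline default is the
non-phylogenetic OLS/bootstrap/Bayes chain; pGLS columns are available behind
`pgls = TRUE`. Polytomies are accepted and never resolved.

## The synthetic-data generator

`generate_specimens()` emulates the structure of the morphometric study this
methodology targets: 10 species, 17 specimens (seven species with two
individuals, three with one), masses log-uniform over 0.097–18 g, and
per-spiracle dimensions following
$\log_{10} y = \log_{10} a + b\,\log_{10} m + \text{phylo} + \varepsilon$
with lognormal noise. Defaults, chosen once as field-realistic values:

* **Exponents** 0.67 (area) and 0.33 (depth) — geometric isometry.
* **Intercepts**: depth 0.1 cm at 1 g for every spiracle; metathoracic area
  1.317 × 10⁻³ cm² at 1 g with multipliers S = 4, T = A1–A3 = 1,
  A4–A6 = 0.5, reproducing the anterior-heavy size pattern (mesothoracic
  ≈ 4× metathoracic; posterior abdominals ≈ half the anterior abdominals).
  The absolute level is set so a 1 g animal's total diffusive conductance is
  ≈ 18 nmol s⁻¹ kPa⁻¹ — equivalently, the largest (18 g) animal needs a
  resting spiracular gradient of roughly half a kPa, the magnitude reported
  for the largest scarabs.
* **Noise** (log10 sd): areas 0.05 (S), 0.08 (T), 0.10 (A1–A3), 0.20–0.25
  (A4–A6) — anterior tighter than posterior; depths 0.08 everywhere,
  independent of area noise.
* **Openings** slit-like with $d_t/d_s = 2$; diameters are back-computed so
  the elliptical area recovers the target exactly.
* **Phylogenetic deviations**: Brownian species effects on a random
  unit-branch-length tree, Pagel-scaled by `lambda_signal` (default 0,
  matching the conclusion that phylogenetic covariance adds no explanatory
  value for such data) with tip-level sd `phylo_sd = 0.1`; the Brownian
  covariance is normalized to unit mean tip depth so `phylo_sd` is directly
  comparable to the noise sds.

The generator matches the *structure* of real data, not any real specimen.
Features of real data it does not emulate include: measurement error
correlated between the two diameters of one opening, sexual dimorphism (sex
is assigned at random and used by nothing), non-power-law curvature, and
spiracle-to-spiracle correlation beyond the shared mass and phylogeny. Tests
passing on generated data therefore validate the estimators and plumbing,
not any biological claim about real beetles.

## Numerical and design choices

* Degenerate inputs: non-positive dimensions or masses error early, naming
  the offending field; fewer than two distinct masses is a degenerate design;
  zero conductance is a domain error for the gradient equation.
* A numerically perfect GLS fit (e.g. a constant response) has unbounded
  likelihood; the profile reports +Inf there, and an all-Inf profile is
  "exactly flat by convention" (flatness 0, degenerate flag).
* Bootstrap degeneracy detection compares resampled masses for exact
  equality, immune to floating-point cancellation in the sums.
* End-to-end determinism: all randomness flows from explicit seeds
  (`set.seed` for R draws, the Mersenne–Twister seed for JAGS), and the
  pipeline's report CSVs are byte-identical across reruns with equal seeds.
* Calibration-simulation sizes are package choices balancing Monte Carlo
  error against runtime: 500 replicates at $B = 2000$ for bootstrap
  coverage (quantile noise at $B = 2000$ is negligible at this precision),
  200 replicates at 1500 draws for HPD calibration, 25 replicates for the
  $\lambda$-flatness study.

## A worked run

```{r example}
cfg <- generator_config(seed = 42)
tree <- generate_tree(cfg)
tab <- generate_specimens(cfg, tree)

caps <- run_capacities(tab)
summary(caps$total_g_diff)

fits <- run_scaling(tab, B = 2000, seed = 42, bayes = FALSE)
fits[fits$spiracle == "total",
     c("metric", "slope", "ci_low", "ci_high", "p_isometry")]
```

The total diffusive slope sits near its isometric expectation of ~0.34 —
far below any metabolic exponent ≥ 0.67 — while the advective slope's
interval overlaps 1: isometric spiracles progressively starve diffusion but
keep pace with (or outpace) advective demand as body size grows.

## Known limitations

* The spiracle is modelled as an elliptical cylinder; real atria are
  bellows-shaped and valved, so conductances are geometric indices, not flow
  measurements.
* No tidal or unidirectional airflow simulation, no valve dynamics, no
  tracheal-network resistance downstream of the spiracle.
* No heteroskedastic or errors-in-variables regression; no model averaging.
* The percentile-bootstrap coverage shortfall at small n described above.
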