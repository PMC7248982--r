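---
title: "Methods: from concentration-time data to a milk withdrawal interval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from concentration-time data to a milk withdrawal interval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkwdi)
```

## The problem

When a drug such as flunixin meglumine is used extra-label in dairy goats,
no regulatory milk withholding time exists and residues of the marker
metabolite (5-hydroxy flunixin) in milk can become violative. `milkwdi`
implements the statistical chain used to derive a defensible withdrawal
interval from a small residue-depletion study: noncompartmental analysis
(NCA) of the plasma kinetics, immunoassay calibration statistics, Monte
Carlo augmentation of sparse milk data, and a regression tolerance-limit
calculation under two regulatory conventions —

* **EMA "safe concentration from linear regression" (SCLR)**: with 95%
  confidence, 95% of animals are below the limit;
* **FDA milk-discard calculation**: with 95% confidence, 99% of animals are
  below the limit, computed on data with at least 10 animals and triplicate
  measurements per sample.

Because studies of this kind publish summary tables rather than raw
per-animal data, the package is built around a simulator with known ground
truth: every stage is validated against analytic results on synthetic
studies that emulate the crossover design (1.1 mg/kg IV and SC, single
doses and q12h x 6), the sampling schedules, the assay CVs (3-6%) and the
LOD/LOQ censoring of a typical goat study.

## The simulator

The plasma model is deliberately the simplest one whose NCA truth is closed
form: a one-compartment parent with elimination rate $k = CL/V$, first-order
SC absorption ($k_a$, bioavailability $F$), and a catenary metabolite formed
at rate $f_m k$ and eliminated at $k_m$ (Bateman kinetics). Multiple doses
combine by superposition. Defaults are calibrated to the magnitudes reported
for lactating goats given flunixin: $CL = 265$ ml/kg/h, $V = 1500$ ml/kg
(terminal half-life just under 4 h), $k_a = 2\,h^{-1}$ (observed SC Tmax
near 1.3 h), $F = 0.90$. Rate coincidences ($k_a \approx k$,
$k_m \approx k$) switch to the analytic limit kernel $t e^{-kt}$ when the
rate difference is below $10^{-8}\,h^{-1}$, so no evaluation ever divides by
a vanishing difference.

Milk has two generators. The *partition* mode multiplies the plasma
metabolite concentration by a milk:plasma coefficient `P_milk`
(instantaneous equilibrium, complete udder evacuation). No study value
exists for this coefficient, so it is a free simulator parameter (default
1.5), not an estimate. The *empirical* mode — the workhorse for the
withdrawal machinery — places the residue peak at the first milking at
least 1 h after the last dose and depletes log-linearly afterwards,
$C(t) = C_0 e^{-\lambda (t - t_{last})}$ with defaults $C_0 = 100$ ng/ml
and $\lambda = 0.1155\,h^{-1}$ (a 6-h depletion half-life). These defaults
put the zero-noise mean-line crossing of the 0.4 ng/ml limit at
$\ln(100/0.4)/0.1155 = 47.8$ h, inside the 36-60 h range regulatory methods
produce for this drug.

Assay error is multiplicative normal with SD equal to the combined CV
$\sqrt{cv_{intra}^2 + cv_{inter}^2}$, truncated at zero. A log-normal model
would be the usual choice for large CVs; at the 3-6% relevant here the
truncated normal is indistinguishable in practice and keeps the moment
checks in the test-suite exact. Values below the LOD are censored with the
number suppressed; values between LOD and LOQ keep their number but are
flagged and excluded from all quantitative use (means, NCA, regression).
Between-animal variability is log-normal around the cohort geometric means.

What the simulator does *not* emulate: two-compartment disposition,
enterohepatic recycling, milk-yield dynamics, disease (mastitis) effects on
excretion, or within-animal correlation of milk residuals beyond the shared
per-animal $C_0$ and $\lambda$. Passing tests therefore demonstrate that
the estimators are correct *for the stated model*, not that the model
captures every feature of field data.

## Noncompartmental analysis

Areas use the linear-up/log-down trapezoid: an interval with falling
concentrations contributes $(C_1 - C_2)\Delta t / \ln(C_1/C_2)$ (and the
matching log first-moment rule), flat or rising intervals the linear
trapezoid. A pure log rule is undefined for equal or rising values, which
is why the hybrid convention is the default; `method = "linear"` switches
to plain trapezoids. AUC is extrapolated with the *observed* last
quantifiable concentration, $AUC_\infty = AUC_{last} + C_{last}/\lambda_z$
— the conventional default of the standard NCA software — rather than the
regression-predicted value.

The terminal slope $\lambda_z$ is chosen by regressing
$\ln C$ on $t$ over every contiguous terminal window of at least three
quantifiable points — starting strictly after Tmax for extravascular
routes, after the first sample for IV — and keeping the window with the
highest adjusted $R^2$ among those with negative slope (ties prefer more
points). A window whose slope is not below $-10^{-10}\,h^{-1}$ is rejected;
on flat data this threshold absorbs floating-point noise that would
otherwise masquerade as an exponential decline. When no window qualifies
the profile still reports Cmax/Tmax/AUClast, and everything downstream of
$\lambda_z$ is `NA` with a diagnostic.

Censoring rules: a pre-dose $t=0$ value below LOQ enters as a true zero and
the leading rise is integrated linearly; censored interior points are
dropped with a gap-spanning trapezoid. Extrapolation of 20% or more is
recorded as a warning in the result, not a failure.

The whole-body extraction ratio divides systemic clearance by allometric
cardiac output $180 \cdot BW^{-0.19}$ ml/kg/min (converted to ml/kg/h). In
consistent units this ratio is dimensionless and necessarily below 1 for
any real drug; published tables for this drug print values above 1, which
cannot arise from the stated formulas in consistent units. The package
computes the consistent dimensionless ratio and makes no attempt to
reproduce those printed values.

## Immunoassay statistics

Calibration uses the four-parameter logistic
$y = D + (A - D)/(1 + (x/C)^B)$ fitted by Levenberg-Marquardt nonlinear
least squares with range-based starting values ($A = \max y$, $D = \min y$,
$C$ = median positive calibrator, $B = 1$). The inverse is closed-form on
$(D, A)$; out-of-range absorbances raise an error mirroring the bench
practice of re-diluting the sample. Assay limits derive from inhibition
concentrations: LOD from the IC10 averaged across plates, working range
from IC15 to IC85, all scaled by the dilution factor.

Method agreement at a time point uses a two-sided F test of variance
equality at $\alpha = 0.05$ followed by a pooled t test (equality not
rejected) or Welch's t. The F test is the classical pre-test; it is
switchable via the `var_alpha` argument and the whole comparison also runs
from (mean, SD, n) summaries so printed tables can be replayed without raw
data. Replaying a summary row with equal means necessarily gives $t = 0$,
$p = 1$; published per-time-point P values computed from unpublished raw
(possibly paired) data are not recoverable from summaries and are not an
acceptance surface. Cross-cohort parameter comparisons use Shapiro-Wilk at
$\alpha = 0.05$ per group, then an unpaired t test (both normal) or
Mann-Whitney. Both two-stage procedures hold their nominal type-I error
within [0.03, 0.07] in the test-suite's 5000-run null simulations.

## Monte Carlo augmentation

The FDA calculation requires ten animals and triplicates; a typical study
has eight animals and single measurements. Each real measurement is
expanded with two replicates drawn from
$\mathcal{N}(value,\ (cv \cdot value)^2)$ at the intra-assay CV (3.2% for
the milk marker assay), and virtual animals are drawn per time point from
the real animals' mean and SD on a common time grid (matching tolerance
0.01 h). Draws are truncated at zero — concentrations are nonnegative and
the truncation bias is negligible at CVs below 6% — and virtual values are
independent across time points, exactly what a per-time-point moment
procedure implies; a correlated-profile alternative is deliberately out of
scope. Real records always pass through byte-identical, augmentation is
unbiased for the per-time-point mean, and an all-zero time point stays
zero in every virtual animal.

## Tolerance-limit withdrawal estimation

The depletion dataset keeps post-last-dose, post-peak milk values strictly
greater than the LOQ (a value exactly at the LOQ is excluded), log-
transforms them, and pools all points across animals in an ordinary
least-squares line $\ln C = a + b t$ — the SCLR convention of independent
points with no per-animal random effect. Two pre-checks are stored with the
fit: a lack-of-fit F test against pure error at replicated times, and a
Bartlett test of variance homogeneity across time groups. They warn rather
than fail by default, because the regulatory tools do not document which
check invalidates a dataset; the slope check is hard — a slope that is not
significantly negative (one-sided, $\alpha = 0.05$) makes the dataset *not
calculable*, and that state propagates as a typed condition, never as a
number.

The upper tolerance limit on the p-th percentile at time $x$ is

$$TL(x) = a + b x + s \sqrt{d(x)}\; t_{\gamma,\ n-2,\ z_p/\sqrt{d(x)}},
\qquad d(x) = \frac1n + \frac{(x - \bar t)^2}{S_{xx}},$$

the classical regression tolerance bound with leverage-dependent
noncentrality. The regulatory tools name their software but not their
formula; this bound is the standard construction beneath both, it is exact
— the coverage of $TL(x)$ at any fixed $x$ is exactly $\gamma$ for normal
errors — and the test suite verifies ~95% coverage by Monte Carlo over
thousands of simulated studies. The withdrawal time is the last
up-crossing of $TL$ against $\ln(\text{limit})$, located on a 512-point
grid over a horizon of ten times the observed span and refined by root
bracketing to $10^{-10}$; EMA uses $p = 0.95$, FDA $p = 0.99$, both at
$\gamma = 0.95$. With a zero tolerance for the drug in goat milk the
operational limit is the marker residue's LOD, 0.4 ng/ml.

Outlier screening flags an animal when the mean of its externally
studentized residuals exceeds 3. "External" is taken at the animal level:
the line is refitted without the animal and its residuals are scaled by the
reduced fit's residual SD and prediction leverage. Point-deletion
studentization from the pooled fit would let a grossly deviant animal
inflate the pooled residual SD enough to mask itself; the animal-level
version detects a twenty-fold deviation immediately while leaving
homogeneous cohorts untouched. At most one exclusion round runs, and an
exclusion that would leave fewer than two animals is an error.

The continuous estimate is rounded *up* to the next multiple of the milking
interval (12 h default); an exact multiple is kept, so 36.0 h stays 36 h
while 34.1 h becomes 36 h, 37.9 h becomes 48 h and 51.5 h becomes 60 h.
Whether the regression runs on natural or base-10 logarithms is immaterial:
the crossing time is invariant to the base (verified to $10^{-9}$ h in the
suite), and observed versus nominal sampling times simply relabel the
x-axis.

## Numerical choices, in one place

* Bateman degeneracy tolerance: $10^{-8}\,h^{-1}$; limit kernel
  $t e^{-kt}$ (and $t^2 e^{-kt}/2$ for the doubly degenerate metabolite).
* $\lambda_z$ slope acceptance: slope $< -10^{-10}\,h^{-1}$; tie-break on
  adjusted $R^2$ within $10^{-12}$ prefers the longer window.
* 4PL fitting: `minpack.lm::nlsLM`, max 200 iterations, $B$ bounded below
  by $10^{-6}$; flat absorbances fail fast with a typed condition.
* Noncentral-t quantiles: `stats::qt(ncp = )`; its reduced-precision
  warning at large noncentrality is suppressed (the loss is orders of
  magnitude below the crossing tolerance).
* Crossing search: 512-point grid, `uniroot` refinement, tolerance
  $10^{-10}$ h; horizon 10x the observed time span.
* Rounding: ceiling to a multiple with $10^{-9}$ slack so that multiples
  up to floating error are not bumped a full interval.
* Time-grid matching for augmentation: 0.01 h.
* Units: hours and ng/ml everywhere internally; doses converted
  mg/kg $\to$ ng/kg ($\times 10^6$); NCA reports concentration-scale
  outputs in ug/ml to match the conventional parameter tables.

## Problem sizes in the test suite

The simulations behind the distributional tests use sizes chosen to make
Monte Carlo error small relative to the tolerance being asserted: 10,000
draws for assay-noise moments, 5,000 animals for cohort geometric-mean
recovery, 2,000 regressions for slope unbiasedness, 5,000 regressions for
tolerance-limit coverage (Monte Carlo SE ~0.3% against a 95% target read
off at a 94% floor), 1,000 paired withdrawal solves for the 99/95 vs 95/95
ordering, and 5,000 null replicates per two-stage test-calibration check.

## Known limitations

* The one-compartment parent underrepresents early distribution kinetics;
  with the rich early sampling schedule this biases nothing the tests
  assert, but parameter recovery tolerances (5% at study sampling) reflect
  discrete-schedule trapezoid error, not model error.
* The pooled SCLR regression ignores per-animal correlation; a
  per-animal-mean sensitivity fit can be had by averaging records per
  animal and time before `fit_depletion_regression()`.
* Augmented datasets inherit the real animals' moments but not their
  profile shapes; FDA results on augmented data are only as representative
  as the eight real profiles.
* The extraction-ratio convention mismatch described above means printed
  values above 1 from other sources cannot be compared directly with this
  package's output.
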