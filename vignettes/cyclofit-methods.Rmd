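---
title: "Models and numerical methods in cyclofit"
author: "cyclofit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in cyclofit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclofit)
```

`cyclofit` covers the quantitative chain of a
drug-in-cyclodextrin-in-liposome formulation study. This vignette
explains each model, its assumptions, the tunable parameters and their
defaults, the numerical choices, what the synthetic-data generators do
and do not emulate, and the package's known limitations.

## Binding equilibria from anisotropy titrations

A fluorescent guest G (the drug) binds a cyclodextrin host H. The
steady-state anisotropy r rises on binding because the complex tumbles
more slowly, so a titration of r against [H] traces the bound fraction.
Two models are implemented:

* **1:1** — f = K[H]/(1 + K[H]), K in dm³ mol⁻¹. The default
  `host_excess` fraction solver assumes the host is undepleted, which
  holds in the usual design (host in mM, guest in µM; at a 100-fold
  excess the approximation is within 0.5% of the exact solution, and
  within 0.1% in the µM-guest regime). The `exact` solver computes the
  physical root of the mass-balance quadratic
  Kc² − (KG + KH + 1)c + KGH = 0 in the cancellation-free product form
  c = 2KGH / (b + sqrt(b² − 4K²GH)), and is cross-checked in the test
  suite against an independent bisection oracle to 10⁻⁹ in fraction.
* **1:2** — f = K[H]²/(1 + K[H]²), with a single *overall* constant K
  in dm⁶ mol⁻². No explicit 1:1 intermediate is modelled: when only an
  overall constant is experimentally resolvable, adding an intermediate
  species constant would be unidentifiable. K^(1/2) (dm³ mol⁻¹) is
  reported alongside for comparison with 1:1 constants.

**Population weighting.** The observed anisotropy is
r = r_free + (r∞ − r_free)·f, i.e. species are weighted by population
fraction rather than fluorescence intensity. This is an assumption: it
is correct when the quantum yield and lifetime of the guest are
unaffected by complexation, which is the case for the camptothecin–CD
systems this package targets. For systems where intensity changes on
binding, fraction weighting biases K; that switch is deliberately not
hidden behind a heuristic — the assumption is stated here and in the
function documentation.

**Estimation.** `fit_binding_isotherm()` minimises the weighted residual
sum of squares over (K, r_free, r∞) by Levenberg–Marquardt (`nls.lm`),
with box constraints K ≥ 0 and anisotropies in (−0.2, 0.4]. Start
values are deterministic and data-driven: r_free from the zero-host
point, r∞ from max(r) + 20%, and K from the double-reciprocal fit (1:1)
or the half-saturation host concentration (1:2). Convergence tolerance
is 10⁻¹⁰ on the relative change in the residual sum of squares, at most
500 iterations. Weights are 1/σ² when a per-point `sigma_r` column is
present, unit otherwise (no error model is imposed on data that do not
carry one). Standard errors come from the local curvature (J'J)⁻¹
scaled by the residual variance.

**Degenerate inputs.** A flat r series leaves K unidentifiable: the fit
flags `amplitude_not_resolved` when the fitted span r∞ − r_free is
below twice the residual scale or below 10⁻⁴ (an anisotropy change no
instrument resolves), and `r_inf<=r_free` when the anisotropy does not
rise. Double-reciprocal linearization refuses data whose transform
yields non-positive slope or intercept — the signature of data
inconsistent with a rising 1:1 isotherm (e.g. a sigmoid).

**Stoichiometry selection** fits both models and compares AICc
(Gaussian likelihood, 4 parameters each including the variance); since
the models have equal complexity this reduces to comparing residual
sums of squares, with exact ties resolved toward 1:1 on parsimony.
A design-of-experiment caveat: the titration grid must span the
half-saturation concentration of the candidate models. A 1:2 complex
with overall K = 10⁸ dm⁶ mol⁻² half-saturates at 10⁻⁴ M; on a 0–12 mM
grid its first nonzero point is already ~99% bound and the two models
are nearly indistinguishable at realistic noise. The simulation grids
in the test suite respect this rule.

**Precision at realistic noise.** With anisotropy noise σ = 0.001, a
12-point 0–14 mM grid, K = 200 dm³ mol⁻¹ and a span of 0.042, the
Cramér–Rao bound gives σ(K̂)/K ≈ 15%. This is a property of the
information content of the design, not of the optimiser; the package's
estimator is essentially unbiased (median relative deviation ~2–3% over
seeded replicates) with 95% Wald intervals covering at their nominal
rate, and that is what the tests assert. Per-temperature fits share
nothing across temperatures — whether r∞ should be common to all
temperatures is a modelling choice we deliberately avoid, fitting each
titration independently.

## Van't Hoff thermodynamics

`vant_hoff_fit()` performs ordinary least squares of ln K on 1/T:
ΔH = −R·slope (kJ mol⁻¹), ΔS = R·intercept (J K⁻¹ mol⁻¹),
R = 8.314 J K⁻¹ mol⁻¹. The regression is unweighted by default because
per-temperature K uncertainties are rarely comparable across media;
optional weights are accepted. The model assumes ΔCp = 0 over the
studied range (5–45 °C) — a nonlinear van't Hoff treatment is out of
scope. Two temperatures interpolate exactly with zero residual and zero
reported standard errors; duplicate temperatures are collapsed by
averaging ln K with a warning. `predict_K()` inverts the relation,
K(T) = exp(−ΔG/(RT)); round trips through fit and prediction are exact
on noiseless grids. Note that constants predicted from tabulated ΔH/ΔS
need not reproduce constants measured by a different technique in a
different medium — such cross-method comparisons are reported, never
asserted.

## Phase solubility

`classify_diagram()` distinguishes the Higuchi–Connors types from a
linear and a quadratic fit of total dissolved drug against [CD]:
A_L when the linear R² ≥ 0.98 with positive slope; A_P / A_N when the
quadratic coefficient is significantly positive / negative at p < 0.05;
B when the upper third of the diagram plateaus or declines. For an A_L
diagram the 1:1 stability constant is K = slope/(S₀(1 − slope)), valid
only for slope < 1.

S₀ is taken from the *diagram intercept*, not from an independently
measured saturation solubility. The two differ whenever the diagram was
acquired with a co-solvent (a few percent of organic solvent changes
the intrinsic solubility): with the intercept convention, K values and
fold-enhancement factors computed from co-solvent-free saturation
concentrations are not mutually derivable, and the package documents
rather than reconciles that tension. `solubility_enhancement()`
optionally rounds to the nearest integer purely for report parity.

## Photophysics

**Anisotropy from polarized intensities.** The L-format expression is
r = (I_VV − G·I_VH)/(I_VV + 2G·I_VH). The denominator is the total
emission of an ideal dipole, I_VV + 2G·I_VH; printed formulations with
a minus sign in the denominator circulate in the literature and are
typesetting errors — the package implements the standard form and says
so in the function documentation rather than silently correcting.

**Decay fitting.** `fit_decay()` fits
I(t) = B + Σ Aᵢ exp(−t/τᵢ) with Poisson weights 1/max(c, 1) — the
correct variance model for counting statistics, under which the reduced
χ² of a well-specified fit is ≈ 1 (the tests assert [0.8, 1.2] at
10,000 peak counts). Tail fitting from the peak channel is the default,
appropriate when lifetimes (~4 ns) far exceed the excitation pulse of
an LED source; IRF reconvolution (discrete convolution with the
normalized response) is available when an `irf` column is present.
Amplitudes and lifetimes are fitted on the log scale, which enforces
positivity without constraints; a constant background is fitted by
default (instrument darkness is rarely zero and fixing it biases long
lifetimes). Start values derive from a log-linear tail regression.
Components collapsing to within 1% of each other trigger a
reduced-model warning; traces with fewer than 50 channels above
background (4σ above the terminal-channel estimate) are refused.

**Stern–Volmer.** The dynamic model I₀/I = τ₀/τ = 1 + K_SV[Q] holds
only at low quencher concentration; static and sphere-of-action effects
curve intensity ratios upward at high [Q]. The "first portion of the
curve" is operationalized as the longest prefix (≥ 4 points, ordered by
concentration) whose linear fit reaches R² ≥ 0.99; if none qualifies
the first 4 points are used with a curvature warning. This rule
recovers the dynamic constant only when the low-concentration region is
genuinely linear — a smooth quadratic deviation reaching back to the
origin biases any prefix slope upward, which is why the curved synthetic
scenario (below) places its static deviation beyond an onset
concentration. k_q = K_SV/τ₀ converts ns to s internally and is
reported in dm³ mol⁻¹ s⁻¹; K_SV stays in dm³ mol⁻¹.

## Loading and release

Encapsulation efficiency is the bare definition
100·encapsulated/total-initial; values published after unstated
dilution or recovery corrections will differ from this ratio, and the
function makes no attempt to guess such corrections (inputs exceeding
100% are clipped with a warning). Release is modelled as an apparent
first-order approach to a plateau, reported as intensity-change
percentages only: fluorescence intensity conflates release with
microenvironment and speciation changes, so converting to absolute drug
mass would overstate what the measurement supports.

`fit_release_first_order()` default (`plateau`) mode operationalizes
"reached a plateau" as: the last 20% of points have a two-sigma
relative spread below 1%. I∞ starts from the plateau mean and is
refined over a few iterations using the current rate estimate, because
the plateau points are still decaying slightly and the uncorrected mean
biases k upward by several percent. k comes from the ln-linear
regression of ln(I∞ − I_t) on t, weighted by the squared fitted
remaining decay (the delta-method weighting that undoes the variance
inflation of the log transform; fitted rather than observed weights so
they are uncorrelated with the noise), excluding points inside the
plateau noise floor whose one-sided truncation would otherwise bias k
downward. `free` mode fits (I∞, I₀, k) jointly and suits truncated
traces. A trace whose four-sigma relative span is below 1% is declared
*stable* — the expected physiological-pH behaviour of an intact
formulation — with k = NA rather than a meaningless fit.

Precision floor: at a 5.5% plateau rise with noise at 0.2% of the
initial intensity and 30 time points, the joint Cramér–Rao bound is
σ(k̂)/k ≈ 5.8% regardless of estimator (and sampling longer does not
help: late points inform I∞, not k). The plateau-mode estimator runs at
~85% efficiency against that bound and is unbiased; the tests assert
recovery at that floor, not beyond it.

## Cytotoxicity

Survival is 100·A_treated/A_control on blank-subtracted absorbances.
`fit_ic50()` uses the four-parameter logistic
S(d) = bottom + (top − bottom)/(1 + (d/IC50)^h) with the top fixed at
100% — the untreated control defines 100% by construction, so freeing
the top would let the control row fit itself — and the bottom bounded
at 0. IC50 is parameterised on the log scale (positivity, and
approximate log-normality of the estimate); with this form
S(IC50) = (top + bottom)/2 exactly. Fits are refused when mean survival
never crosses 50%, where an IC50 would be an extrapolation. Replicate
columns can be fitted separately (`per_replicate = TRUE`); those
replicate IC50s feed `compare_ic50()`, a two-tailed equal-variance
Student's t-test on log IC50. The equal-variance form is the named
classical test; the log scale matches the error structure of
concentration estimates. Its type-I error at n = 3 per group is
calibrated (asserted within [0.025, 0.085] at nominal 0.05 over 2000
null simulations). Whether dose-response studies should fit per
replicate or on pooled means is genuinely open; both are provided, with
per-replicate the default route into the t-test.

## Synthetic data: what it does and does not emulate

The `synth_*` generators produce every input format the package
consumes, with the statistical structure the estimators assume:
Gaussian anisotropy noise on titrations (defaults: 12 points, 0–12 mM
host, σ_r = 0.001, the span of published anisotropy precision);
multi-temperature series derived from (ΔH, ΔS) through the van't Hoff
relation so the thermodynamics stage is exercised end to end (defaults
ΔH = −26.2 kJ mol⁻¹, ΔS = −56.1 J K⁻¹ mol⁻¹, a PBS-like
enthalpy-driven parameter set; K ≈ 46 dm³ mol⁻¹ at 25 °C); an overall
1:2 constant of 5 × 10⁴ dm⁶ mol⁻² (three orders of magnitude above the
1:1 constants, half-saturating at ~4.5 mM, i.e. sigmoidal within the
titration window); A_L solubility diagrams from (K, S₀); TCSPC
histograms of 1024 channels over 100 ns with 10,000 peak counts and
Poisson noise; Stern–Volmer series with an optional threshold-quadratic
static deviation (linear at the lowest concentrations, curving beyond
an onset — the regime in which first-portion analysis is valid);
first-order release plateaus (k = 0.0103 min⁻¹, 5.5% rise, 600 min);
and triplicate 4PL plates (IC50 = 17 nM, Hill 1.5, σ = 5 percentage
points).

Each generator records its true parameters in a `truth` attribute, and
`generate()` writes them to a JSON sidecar, so recovery tests never
re-enter true values by hand. Identical configurations and seeds yield
byte-identical files.

Deliberately *not* emulated: inner-filter effects, photobleaching,
scatter peaks and IRF colour shift in the photophysics; co-solvent
activity effects in solubility diagrams; dialysis mass-transfer
kinetics; plate-edge and batch effects in MTT data. Passing tests on
synthetic data therefore demonstrate correctness of the estimators
under their stated error models — not robustness to instrument
artefacts, which real data may add.

## Problem sizes in the test and acceptance suites

The seeded simulations use 200 replicates for parameter-recovery and
coverage checks, 50 replicates per arm for stoichiometry selection,
1000 random points for the solver-versus-oracle comparison, and 2000
null simulations for t-test calibration — sizes at which the asserted
proportions have comfortable Monte-Carlo margins while the whole suite
runs in seconds.

## Known limitations

* Host-deficient (2:1) complexes, explicit 1:1 intermediates in the
  1:2 model, and nonlinear van't Hoff analysis are out of scope.
* Time-resolved anisotropy decays and global multi-wavelength analysis
  are not implemented; anisotropy is steady-state only.
* The linear-region rule for quenching is a heuristic; strongly curved
  series with no linear onset yield a flagged 4-point fit whose slope
  should be treated as an upper bound on K_SV.
* Release percentages are semi-quantitative by design; no conversion to
  released drug mass is attempted.
* IC50 standard errors are local (curvature-based); profile or
  bootstrap intervals are not provided.
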