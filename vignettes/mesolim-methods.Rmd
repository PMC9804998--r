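---
title: "Methods: standardising, filtering and modelling mesophyll conductance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardising, filtering and modelling mesophyll conductance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesolim)
```

`mesolim` implements a complete analysis chain for compilations of leaf
mesophyll conductance ($g_m$) measurements: standardisation to common
units and conditions, quality control, quantification of the
photosynthetic limitation imposed by $g_m$, and trait regressions. This
vignette records the scientific and numerical choices behind each stage,
in the order the pipeline runs them.

## The quantity and its standardisation

$g_m$ is defined through Fick's first law, $g_m = A_n/(C_i - C_c)$, with
$A_n$ net photosynthesis (μmol m⁻² s⁻¹), $C_i$ the intercellular and
$C_c$ the chloroplastic CO₂ mole fraction (μmol mol⁻¹). Values reported
in liquid-phase equivalent units are converted to a molar flux basis:
1 μmol m⁻² s⁻¹ Pa⁻¹ equals 0.1 mol m⁻² s⁻¹ bar⁻¹, and a bar-basis value
times the atmospheric pressure in bar gives mol m⁻² s⁻¹. Pressure is
taken from the record; when only elevation $z$ (m) is available we use
the international barometric formula
$P = 101.325\,(1 - 2.25577\times10^{-5} z)^{5.25588}$ kPa, and when
neither is reported 100 kPa (= 1 bar) is assumed. If a source reports
stomatal conductance on a water-vapour basis, `gs_water_to_co2()` divides
by 1.6, the ratio of the molecular diffusivities of water vapour and CO₂
in air.

Temperature standardisation to 25 °C divides $g_m$ by a scaling factor
$f(T)$ with $f(25) = 1$. Two parameterisations are shipped in
`inst/extdata/tresponse.yaml`:

* `tobacco` (default) — a peaked Arrhenius function,
  $f(T) \propto e^{c - H_a/(R T_k)} / (1 + e^{(S T_k - H_d)/(R T_k)})$,
  with $c = 20.01$, $H_a = 49.6$, $H_d = 437.4$ kJ mol⁻¹ and
  $S = 1.4$ kJ mol⁻¹ K⁻¹, transcribed from the tobacco measurements this
  response was originally fitted to.
* `arabidopsis` — a weak non-peaked Arrhenius response
  ($E_a = 20.2$ kJ mol⁻¹), used to probe how sensitive downstream
  statistics are to the standardisation choice. Its defining property,
  the one tests rely on, is that it deviates less from unity than the
  tobacco response at any temperature in the filter window.

Because the parameters are transcriptions, the code renormalises $f$ so
that $f(25) = 1$ holds to machine precision regardless of the absolute
scale of the transcription; a transcription-scale error therefore cannot
shift the reference point. Records flagged `already_standardised` bypass
scaling, and the value at the original measurement temperature is always
retained alongside $g_{m,25}$, so analyses that pair $g_m$ with other
measurements made at the same temperature remain possible.

## Quality control

Four deterministic filters classify records (they never raise errors):
measurement temperature outside 15–35 °C *or missing*; irradiance below
300 μmol m⁻² s⁻¹; measurement CO₂ outside 300–500 μmol mol⁻¹; and a CO₂
drawdown $A_n/g_m$ above 300 or below 10 μmol mol⁻¹. Missing temperature
excludes a record because the temperature standardisation is undefined
without it; missing irradiance or CO₂ does **not** exclude — the record
is retained and counted in a `missing_log`, a deliberate choice where
the defensible alternatives (exclude or retain) are both plausible, made
configurable through `qc_thresholds()` and recorded per run so a rerun
against a deposited dataset can arbitrate.

Outlier detection is two-step and strictly ordered. Step 1 removes
extreme values above 2 mol m⁻² s⁻¹ (herbaceous) or 1 mol m⁻² s⁻¹
(woody). Ferns and other groups that are neither get the woody threshold:
their observed $g_m$ range is low, so the stricter bound is the safer
default (configurable). Step 2 log-transforms the survivors and flags,
separately per PFT, values outside $[Q_1 - 1.5\,\mathrm{IQR},
Q_3 + 1.5\,\mathrm{IQR}]$. Quartiles use linear interpolation (type 7,
R's default) — the convention most software defaults to; the natural log
is used and fences are never back-transformed (flags are set
membership). Groups smaller than 4 skip step 2, since quartiles of three
points carry no outlier information. Step-1 removals never enter the
step-2 quartile computation.

When one plant set was measured with several methods, curve-fitting
estimates are superseded by the other method when exactly one exists;
two non-curve-fitting methods are averaged; combinations beyond these
(three or more methods) fall back to the mean of the non-curve-fitting
values and are logged as out-of-rule cases.

## Photosynthetic limitation

The relative limitation imposed by $g_m$ is
$L_m = (A_{np} - A_n)/A_{np} \times 100$, where $A_{np}$ is
photosynthesis at $C_c = C_i$ — infinite mesophyll conductance with
stomata as measured. $L_m$ is scale-invariant in $(A_n, A_{np})$ and
lies in $[0, 100)$ for physical inputs; $A_n > A_{np}$ (an inconsistent
source report) yields a negative value with a warning rather than an
error.

The limitation curve $L_m = a\,e^{-b g_m}$ is fitted by direct nonlinear
least squares on the original scale (Levenberg–Marquardt), not by
log-linearisation — the latter would re-weight the small-$L_m$ tail.
Start values come from a linear fit of $\log L_m$ on $g_m$ over the
positive pairs, with a small restart grid as a fallback. $b$ is stored
positive with the minus sign in the model. Point exclusion is an
explicit caller-supplied id list, never automatic, mirroring how single
anomalous species are excluded by judgement in published fits.

No analytic confidence band is attached to the curve because the
published analyses this machinery supports do not state their CI
construction; we use a seeded nonparametric case-resampling bootstrap
(1000 resamples by default, percentile 95% band). Per-PFT limitation
ranges combine the band with the PFT's interquartile $g_m$ range in the
widest defensible way: the lower bound of the band at $Q_3$ (high
conductance, low limitation) to the upper bound at $Q_1$. The
alternative reading (point curve at the quartiles) is available via
`rule = "point"`.

## Trait statistics

Because $g_m$ compilations are strongly right-skewed, $g_{m,25}$ is
modelled with a gamma GLM and log link:
$\log E[g_{m,25}] = \beta_0 + \beta_1 S_c + \beta_2 T_{cw}$, with $S_c$
the chloroplast surface area exposed to intercellular airspaces per leaf
area (m² m⁻²) and $T_{cw}$ the cell-wall thickness (μm). Coefficients
are reported as $e^\beta$, so a one-unit trait increase multiplies the
expected $g_{m,25}$. Intervals are Wald on the link scale
(Pearson-χ² dispersion), exponentiated — profile-likelihood intervals
would also be defensible; Wald was chosen and is stated in the output so
the choice is auditable. Fit quality is McFadden's pseudo-$R^2$,
$1 - \ln L(M_{full})/\ln L(M_{null})$. Note a property of this
definition for continuous responses: it is only interpretable (in
$[0,1)$) when both log-likelihoods are negative. On near-noise-free data
the gamma likelihood grows without bound and the ratio is reported as
`NA`; on tightly dispersed synthetic data it can be negative. This is a
property of the statistic, not of the fit.

Pairwise trait relationships use M-estimation with the Tukey bisquare
psi function (tuning constant 4.685 for 95% Gaussian efficiency), IRLS
to a 1e-8 relative tolerance or 50 iterations. The linear case is
standard M-estimation; the power-law case $y = a x^b$ runs the same
bisquare reweighting around a Levenberg–Marquardt step on the original
scale, started from a robust fit of $\log y$ on $\log x$, with the
residual scale re-estimated each iteration by the MAD. Exactly collinear
data are short-circuited to least squares (the M-scale collapses there).
The $R^2$ attached to robust fits is the weighted variant
$1 - \sum w r^2 / \sum w (y - \bar y_w)^2$ with the final IRLS weights —
robust fits have no unique $R^2$, so the definition is stated here and
in the object. Exact numerical agreement with other robust-regression
implementations is not a goal; the estimator is specified instead.

Group medians are compared with Dunn's rank-based test with tie
correction and Holm adjustment (configurable). Any relationship is
`reported` only when $n \ge 12$ — a pre-registered reporting gate, not a
fitting restriction; the threshold is configurable. All regressions are
pairwise-complete: each uses the rows where both variables are present,
so sample sizes vary legitimately across analyses.

## The synthetic-data generator

`simulate_leaf()` couples a Rubisco-limited demand curve
$A = V_{cmax}(C_c - \Gamma^*)/(C_c + K_m) - R_d$ to the diffusive supply
chain $C_c = C_a - A(1/g_{s,c} + 1/g_m)$. Substitution yields a
quadratic in $A$; the physical root is the one with $C_c \in (0, C_a)$.
$A_{np}$ is solved identically with $1/g_m = 0$, which operationalises
the definition of $L_m$. Defaults ($\Gamma^* = 42.75$,
$K_m = 717$ μmol mol⁻¹ at 25 °C, $V_{cmax} = 80$,
$R_d = 1$ μmol m⁻² s⁻¹, $g_{s,c} = 0.25$ mol m⁻² s⁻¹, $C_a = 400$
μmol mol⁻¹) are standard literature constants; no test depends on their
values, only on the coupling identities and on qualitative behaviour
(monotone decrease of $L_m$ in $g_m$, the ~35–55% limitation band below
$g_m = 0.1$ mol m⁻² s⁻¹).

`generate_cohort()` emulates the structure of a compiled dataset:
PFT-stratified records whose $g_{m,25}$ follows the log-linear trait
link above with multiplicative gamma noise (mean-preserving, shape 5 by
default), trait covariates drawn uniformly over PFT-specific ranges
($S_c$ within 5–40 m² m⁻², $T_{cw}$ within 0.05–0.6 μm, narrower per
PFT), measurement temperatures mostly at 25 °C with a U(18, 32) °C
remainder, and methods/study identifiers assigned at random. Default
per-PFT sample sizes (25–60, 265 rows total) keep every recovery test
fast while leaving each PFT large enough for the outlier screen.
Photosynthetic capacity co-varies with conductance
($V_{cmax} \approx 400\,g_{m,25}$, clamped to 10–150 μmol m⁻² s⁻¹,
lognormal spread) and $g_{s,c} \approx 1.3\,g_m$ — the observed
coordination between diffusive and biochemical capacity — which keeps
simulated CO₂ drawdowns in the physically typical range, so a cohort
with no planted violations passes every filter.

What the generator does **not** emulate: between-study systematic offsets
(method biases are random, not structured), measurement error in the
traits, phylogenetic structure, and any electron-transport-limited
photosynthesis (the demand curve is Rubisco-limited only, adequate for
the light-saturated measurements such compilations represent). Passing
recovery tests on these cohorts therefore demonstrates the correctness
of the estimators under the model's own assumptions, not robustness to
every failure mode of real compilations.

`inject_violations()` plants labelled violations of exactly one
criterion per selected row (10 °C; 200 μmol m⁻² s⁻¹ PPFD; 600 μmol mol⁻¹
CO₂; $g_m$ lowered until the drawdown passes 300 μmol mol⁻¹; $g_{m,25}$
inflated 25% past the extreme threshold). Planted rows keep their other
fields inside the filter windows so ground-truth labels map one-to-one
onto criteria, which is what makes exact precision/recall checks
possible.

## Numerical and reproducibility choices

* All nonlinear optimisation uses Levenberg–Marquardt
  (`minpack.lm::nlsLM`), which converges cleanly on zero-residual data
  where Gauss–Newton step-halving fails.
* Quantiles everywhere are type 7; changing the convention shifts IQR
  fences only for tiny groups.
* Every stochastic component (cohort generation, violation planting,
  bootstrap) takes an explicit integer seed, and identical seeds give
  byte-identical outputs. The pipeline manifest records package version,
  seed, temperature-response choice and a config hash.
* Test problem sizes — cohorts of 265 rows, 100-replicate recovery
  loops at $n = 295$, 1000-group fence checks — were chosen as the
  smallest sizes at which the statistical assertions are stable.

## Known limitations

* The gamma GLM fits no study-level random effects; records from one
  study are treated as independent, as in the analyses this package
  mirrors.
* The per-PFT limitation ranges depend on a bootstrap band whose exact
  construction is a package choice (percentile, case resampling);
  endpoint-level agreement with other CI constructions is not expected.
* PFT labels outside the six analysed groups are carried as `other` and
  excluded from PFT-level statistics; the package does not attempt
  taxonomy resolution or classification of records with missing habit
  metadata beyond the configurable mapping table in `assign_pft()`.
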