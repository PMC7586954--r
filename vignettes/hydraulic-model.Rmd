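---
title: "The soil-plant hydraulic model behind planthydro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The soil-plant hydraulic model behind planthydro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planthydro)
```

planthydro links measurable xylem hydraulic traits of cotton genotypes to
whole-plant behaviour under drought. This vignette is the package's account
of the science: the model pieces, their assumptions, the parameters that
matter, and the choices we made where the design was genuinely open.

## Vulnerability curves

Loss of xylem conductivity with tension is described by a two-parameter
Weibull curve,

$$K_s(\psi) = K_{smax}\, e^{-(-\psi/b)^c}, \qquad
  PLC(\psi) = 100\,\bigl(1 - e^{-(-\psi/b)^c}\bigr),$$

with scale $b$ (MPa, stored as a positive magnitude) and shape $c$
(dimensionless). Cotton curves are strongly "R-shaped" ($c < 1$): a rapid
decline at mild tension followed by a long tail. The summary statistic P50
has the closed form $\psi_{50} = -b (\ln 2)^{1/c}$; with the packaged
species-level parameters (shoot $b = 1.55$, $c = 0.75$; root $b = 0.29$,
$c = 0.59$) it evaluates to $-0.95$ and $-0.16$ MPa. Note how shallow the
root curve is: roots have lost roughly 40% of their conductivity by
$-0.1$ MPa. That single number drives much of the whole-plant behaviour
below.

`fit_vc()` estimates $(b, c)$ by bounded Levenberg–Marquardt least squares
from a 3×3 multistart grid ($b_0 \in \{0.2, 1, 3\}$,
$c_0 \in \{0.5, 1, 2\}$, bounds $b \in (0.01, 20]$, $c \in (0.05, 20]$);
R-shaped curves produce flat, bent residual surfaces on which single-start
fits are fragile. PLC-scale fits supply the simulator's parameters;
$K_s$-scale fitting (with $K_{smax}$ fixed or co-estimated) is provided for
completeness. Genotype comparisons (`compare_vc_parameters()`) use one-way
ANOVA with Tukey HSD at $\alpha = 0.05$ on replicate-level parameters.

## Soil texture to soil hydraulics

Field texture is mapped from sparse borings with ordinary block kriging
(`fit_variogram()`, `block_krige()`): an empirical semivariogram binned by
lag, fitted by pair-count-weighted least squares to an exponential
(default) or spherical model, then a standard ordinary-kriging system with
Lagrange multiplier and block support via a 4×4 midpoint discretization.
Weights sum to one per block by construction, and with a zero nugget the
predictor interpolates the samples exactly. Clay and sand are kriged
independently per 30-cm depth layer and silt closes the composition; this
avoids log-ratio compositional machinery at the cost of a clip at the
boundary, which in practice never binds for these field ranges. Grid cells
average ten member plots, and cells at or beyond the 10th/90th clay
percentiles (linear interpolation between order statistics, boundaries
included) define the contrasting low-clay (LC) and high-clay (HC)
conditions.

Texture converts to Brooks–Corey retention and conductivity parameters via
the Rawls–Brakensiek regression family (clay %, sand %, porosity as
predictors), implemented as a named coefficient table so a different
pedotransfer variant can be swapped in. Retention is
$\psi = \psi_e S_e^{-1/\lambda}$ and conductivity
$K(\theta) = K_s S_e^{3 + 2/\lambda}$. Field capacity and permanent wilting
point are the retention inverse at $-33$ and $-1500$ kPa. For the packaged
textures the HC soil is more retentive and, at equal water content in the
dry range, sits at a more negative matric potential than the LC soil — the
mechanism behind the soil-contingent behaviour explored below. Because the
source regressions are published in several variants, the package's tests
assert orderings and invariants of the pedotransfer outputs rather than
absolute values.

## The supply–demand continuum

The plant is a network: a Weibull shoot element in series with parallel
root branches, one per soil layer, each root element in series with a
rhizosphere element whose linear conductance follows $K(\theta)$ scaled by
the root area in that layer (leaf-area basis: root:leaf area ratio × layer
fraction) over a path length expressed in multiples (default 100) of the
soil's geometric mean particle diameter. For a Weibull element the
Kirchhoff transform (matric flux potential) has the closed form

$$W(\psi) = b\,\Gamma(1 + 1/c)\, Q\!\left(\tfrac{1}{c},
  \bigl(\tfrac{-\psi}{b}\bigr)^{c}\right),$$

with $Q$ the upper regularized incomplete gamma function, and $W$ is
invertible through the gamma quantile function. Flux through an element is
its saturated conductance times a difference of $W$ values, so the network
solve reduces to one-dimensional root finding: a safeguarded Newton
iteration per layer for the rhizosphere/root series, and a safeguarded
Newton with the analytic derivative for the root-crown potential. The
critical transpiration $E_{crit}$ — the supremum of the supply function,
finite for Weibull elements — is the crossing of the root system's supply
(increasing as the crown potential falls) with the shoot's remaining
capacity (decreasing). For a single saturated element this yields the
closed form $E_{crit} = k_{max}\, b\, \Gamma(1 + 1/c)$, which the test
suite uses as an oracle.

### Anchoring element conductances

The measured reference state gives the saturated whole-plant conductance
$k_{max} = E_{sat} / (\psi_{pd} - \psi_{md}) = 11.4 / 1.6 = 7.125$
mmol m⁻² s⁻¹ MPa⁻¹. Saturated element conductances carry a 50/50
root/shoot resistance split, but a split of $k_{max}$ alone cannot
reproduce the reference state: with the measured root curve the root
element is already ~84% cavitated at $-0.8$ MPa, so the elements need more
saturated capacity than the composite conductance suggests. We therefore
scale both sides by a single multiplier solved at network build time so
that the fully charged state (all layers at $\psi_{soil} = 0$, flux
$E_{sat}$) returns $\psi_{leaf} = \psi_{md}$ exactly. For the species
parameterization on the LC soil the multiplier is ≈ 2.31. For
genotype-contrast experiments the multiplier is solved once for the
species-level curves and reused for every genotype on that soil
(`calib_mult` in `sim_config()`), so in-silico genotypes differ *only* in
vulnerability-curve shape; re-calibrating per genotype would compensate
away precisely the contrast under study.

### Demand and regulation

Stomatal demand follows the Oren form
$G_s = G_{sref}(1 - m \ln D)$, clipped at zero (closure at
$D = e^{1/m} \approx 5.3$ kPa for the fixed literature slope $m = 0.6$),
times a saturating light factor equal to 1 at the 2000 µmol m⁻² s⁻¹
gas-exchange reference, and converts to flux as $G_s (D/P_{atm})$ per unit
leaf area. Demand above 90% of the instantaneous $E_{crit}$ (configurable
`cap_frac`) is capped and the step flagged — a stomatal-closure rule that
prevents the runaway flank of the supply curve. Element conductivities are
recomputed from current-step potentials (no cavitation memory): the curves
were measured after flushing, and over a single season for a crop we treat
conductivity loss as recoverable; a no-refilling variant would be a
straightforward extension but is not implemented.

Canopy temperature is a single-leaf energy balance,
$T_c = T_{air} + (R_{n,abs} - \lambda E) / (\rho_a c_p g_H)$, with absorbed
net radiation defaulting to half the shortwave implied by PAR scaled by
canopy light interception, and a wind-based heat conductance
$g_H = 0.04\sqrt{u}$. Both defaults are coarse and exposed as arguments;
the term exists to mirror the thermal validation surface, not to close an
energy budget.

## The season loop

`run_simulation()` integrates half-hourly over day-of-year 160–240 (3840
steps for the standard 80-day window) with five 30-cm soil layers matching
the sampling scheme. Step order: (1) infiltrate water input top-down,
filling each layer to field capacity before passing excess (excess past
the bottom layer leaves as drainage); (2) stomatal demand; (3) continuum
solve; (4) uptake removal per layer; (5) layers above field capacity relax
toward it at 0.5 day⁻¹, cascading downward. The water balance closes to
floating-point error by construction, and the suite asserts a residual
below 10⁻⁴ mm over the full window. Initial water content defaults to
field capacity; there is no soil-evaporation term (the focus is plant
hydraulics, and the arid-summer forcing has almost no rain wetting the
surface outside irrigation events). The root:leaf area ratio (packaged
value 2.5) can be re-calibrated against layered soil-moisture observations
by grid search on the mean across-layer RMSE (`calibrate_root_ratio()`).

## Stress metrics and experiments

Per-day metrics use half-open windows in local standard time — predawn
03:00–05:00 and midday 12:00–14:00, four half-hourly steps each. From the
midday aggregates: the hydraulic safety margin $E_{crit} - E_c$; the
relative safety margin $\rho$ (margin normalized by its seasonal maximum,
in $[0,1]$); percent loss of whole-plant conductance
$PLK = 100(1 - k_{plant}/k_{max})$, clamped with a warning if the chord
conductance transiently exceeds $k_{max}$ in wet low-flux states; and the
normalized midday transpiration difference
$\delta_i = (a_i - b_i)/\mathrm{mean}(a_i, b_i)$ between two genotype
runs. A day is a divergence day when $\delta$ under the HC and LC soils
have strictly opposite signs (a zero $\delta$ never flags — conservative
flip detection), and windows are maximal runs of two or more consecutive
flagged days with the same orientation.

Drought scenarios E1–E3 share identical forcing before day 188; E2 and E3
then receive 50% and 25% of E1's per-step water input. `run_experiment()`
orchestrates three factorials: validation (WW/WL irrigation × HC/LC,
staged leaf area), sensitivity (five stem-VC parameter sets × E1–E3 on the
field-mean 24–58–18 clay-sand-silt soil at fixed LAI 3.5), and the G×E
factorial (two contrasting genotypes × two soils × three scenarios, 12
runs).

## The synthetic study conditions

All inputs are generated, seed-deterministically, by the `gen_*` functions;
the defaults define the study conditions and were chosen once:

* **Forcing**: low-desert Arizona monsoon-season summer at latitude 33.07 —
  solar-geometry PAR peaking near 2000 µmol m⁻² s⁻¹, air temperature
  23–36 °C with 1.5 °C day-to-day variation, VPD against an 18 °C
  dewpoint, wind ~2 m s⁻¹, near-zero rain.
* **Irrigation**: the scenario base gives 16 mm every 2 days (slightly
  below unstressed demand, so E1 is the least severe but not stress-free);
  the well-watered validation regime gives 18 mm daily, which the suite
  verifies never trips the supply cap; the water-limited regime keeps 25%
  of that after day 188.
* **Genotype presets**: stem-VC scale parameters anchored to the measured
  genotype P50 values (PD3 $-1.52$, Tipo Chaco $-0.49$ MPa) at the species
  shape $c = 0.75$. The DP1549 and Coker presets are *synthetic stand-ins*
  ($-1.20$ and $-1.05$ MPa) since their individual fits are not published;
  they are labelled as such in the documentation.
* **Soil fields**: clay as a Gaussian random field (mean 0.24, sill
  0.0025, exponential range 30 m, 10% nugget) over a 120 × 60 m extent in
  five depth layers, silt weakly co-varying, sand by closure.

What the generators do *not* emulate: real weather autocorrelation beyond
a daily AR term, advection in the energy balance, observation gaps,
plot-level management noise, or the actual season the field campaigns
experienced. Passing tests therefore demonstrate internal consistency and
qualitative reproduction of the published behaviour — curve shapes,
orderings, conservation, ranking flips — not numerical agreement with the
original field runs, whose forcing and observations were never deposited.

## Numerical choices and limitations

Solvers are bracketed throughout: safeguarded Newton with bisection
fallback for layer fluxes (tolerance 10⁻¹¹ relative) and for the
root-crown and critical-flux solves (10⁻¹⁰), with soil potentials floored
at −1000 MPa to keep the gamma-function arguments finite. Zero-demand
night steps reuse the previous solve when the soil state is unchanged —
identical inputs, identical outputs — which roughly halves runtime. The
standard 80-day run takes on the order of ten seconds on one core; the
12-run factorial about two minutes.

Known limitations: no carbon assimilation, allocation, growth or yield
(leaf area is prescribed); no soil evaporation or groundwater; a
single-leaf energy balance without boundary-layer profiles; isotropic
variograms and non-compositional kriging; stomatal behaviour is entirely
supply-capped Oren demand, so midday depressions at high VPD follow the
log form even where field cotton shows residual conductance. Within those
bounds, the package reproduces the qualitative structure it was built to
study: steeper stem vulnerability buys a conservative water-use strategy
whose relative safety margin advantage grows with drought severity, and
genotype rankings of midday transpiration can flip with soil texture in a
time-dependent way.
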