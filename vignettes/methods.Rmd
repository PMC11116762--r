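---
title: "Methods: estimating and attributing vegetation CO2-sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and attributing vegetation CO2-sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegsens)
```

## The model

The sensitivity β of gross primary production (GPP) to atmospheric CO₂ is
defined relatively: the percent increase in GPP per 100 ppm of CO₂. It is
estimated per grid cell by ordinary least squares within a moving window,

$$GPP_t = \beta\,CO2_t + a_1\,VPD_t + a_2\,T_{max,t} + a_3 + \varepsilon_t,$$

where the covariates control for the two confounders most tightly coupled
to the CO₂ trend: vapor pressure deficit and maximum temperature. OLS with
an intercept is the maximum-likelihood solution under i.i.d. Gaussian
errors; no robust or generalised variant is in scope. The raw coefficient
(GPP units per ppm) is normalised by the window-mean GPP:

$$\beta_{rel} = \hat\beta \times 100\,\mathrm{ppm} \,/\, \overline{GPP}_w \times 100\%.$$

Key numerical choices:

* **Window geometry.** 15 years, stride 1, each window labelled by its
  centre year. Centre labelling is symmetric, so the subsequent trend fit
  over window positions carries no phase bias. An `n`-year record yields
  `n − 14` windows.
* **Missing data.** A window containing any masked year is skipped for that
  pixel, rather than fitted on a reduced sample; this keeps window-to-window
  composition constant at the cost of coverage.
* **Collinearity guard.** CO₂, VPD and Tmax all trend upward and can be
  nearly collinear within 15-year windows. Designs whose condition number
  exceeds 1e8 (or that are rank deficient, e.g. constant CO₂) are flagged
  invalid and masked, never silently returned.
* **Degenerate trend fits.** The per-pixel trend engine (used for β series
  and for any gridded variable) needs ≥ 3 valid points; an exact-fit series
  (zero residual) gets p = 0 for a nonzero slope and p = 1 for a zero one.
  P-values come from the t distribution with n − 2 degrees of freedom, with
  no autocorrelation correction — window overlap makes successive β
  estimates strongly dependent, so single-pixel significance is optimistic
  and the package's own recovery checks rely on across-seed spreads
  instead.

## VPD physics

Saturated vapor pressure uses a Magnus-type form with a moist-air
enhancement factor,

$$f = 1 + 7\times10^{-4} + 3.46\times10^{-6} P_a, \qquad
SVP = 6.112\, f\, e^{17.67\,T/(T+243.5)},$$

with air pressure from the barometric relation
$P_a = 1013.25\,((T+273.16)/(T+273.16+0.0065H))^{5.625}$. The 273.16 offset
inside this formula is reproduced as printed in the formulation this
implements, even though Kelvin conversion at ingestion subtracts 273.15.
VPD is defined as $SVP - AVP$ (the standard meteorological deficit; the
source formulation computes both pressures and leaves the subtraction
implicit). Two humidity dialects are supported — relative humidity
($AVP = RH/100 \cdot SVP$) and directly ingested actual vapor pressure —
and agree to 1e-12 on consistent inputs. Elevation defaults to 0 (sea-level
pressure) unless a grid is supplied, since typical humidity reanalyses do
not name one. RH marginally above 100 (reanalysis supersaturation
artifacts) is clipped to 100 with a warning, keeping VPD ≥ 0; RH beyond 105
is treated as an error, not an artifact.

The stomatal identity $A = T\,C_a/(1.6\,VPD)\,(1 - C_i/C_a)$ is included as
the mechanistic rationale: at fixed transpiration and CO₂ partial
pressures, assimilation is inversely proportional to VPD.

## Attribution

Windowed β series are regressed on driver series averaged over the *same*
windows: VPD, water availability (precipitation − ET), N deposition and P
deposition (historical mode) or soil N in place of the depositions (future
mode, where P-deposition outputs do not exist). The regression includes an
intercept even though the canonical form omits it — without one, mean
offsets leak into the coefficients. Standardized coefficients
$Stc_X = |a_X|\,sd(X)/sd(\beta)$ are normalised into shares
$R_X = Stc_X/\sum_Y Stc_Y$, which are non-negative and sum to 1 by
construction; signed coefficients remain available for inspection. Two
conventions deserve note:

* The denominator is $sd(\beta_m)$. The printed symbol in the source
  formulation ("std(CO2−WUE)") is defined nowhere; its surrounding text
  combines the standard deviations of the driver and of β, which is the
  ordinary standardized-coefficient recipe, so the text governs.
* Absolute values are taken *before* normalisation, as required for shares
  that are non-negative and sum to one.

A partial-correlation cross-check (residual-on-residual, controlling each
driver for all others) is reported separately; it is the tool for
separating VPD from the temperature it is computed from. Pixels with
rank-deficient designs, fewer than k + 2 windows, constant β, or all-zero
standardized coefficients are masked, never imputed.

Regional summaries weight pixels by cos(latitude) (cell areas on a regular
lat-lon grid shrink poleward); a cell-count mode exists for comparison, as
do pooled "nutrient" (N + P) summaries. The region of interest defaults to
cells at ≥ 30° N — the northern middle and high latitudes — with the bound
configurable because definitions vary.

## The synthetic world

`generate_scenario()` emulates the statistical structure the analysis
assumes, with defaults fixed once:

| quantity | default | rationale |
|---|---|---|
| grid | 10×10, 30–90° N | recovery-test scale |
| years | 1982–2015 | one 34-year record, 20 windows |
| CO₂ | 341 ppm + 1.9 ppm yr⁻¹ | near-linear observed rise |
| β_rel | 20 % /100 ppm, trend −0.05 yr⁻¹ | plausible magnitude; injected decline |
| warming | +0.03 °C yr⁻¹ | northern land warming |
| RH | −0.05 % yr⁻¹ | mild drying so VPD rises under warming |
| implied VPD trend | ≈ 0.013–0.015 hPa yr⁻¹ | the stated driver structure |
| precip / ET | +0.044 / +0.02 mm month⁻¹ yr⁻¹ | water supply outpacing demand |
| N deposition | rise, then −6 mg m⁻² yr⁻² after 1990 | post-1990s policy decline |
| P deposition | +0.5 mg m⁻² yr⁻² | slight rise |
| GPP noise | sd = 2% of baseline | placeholder; observed residual structure is unreported |

GPP couples the sensitivity trajectory multiplicatively,
$GPP_t = G_0 e^{F_t} + c_1 VPD'_t + c_2 T'_{max,t} + \epsilon_t$, with
$F_t$ the trapezoid-accumulated $\sum\beta_{true}(s)\,\Delta CO2_s/10^4$.
Three design points matter:

* **Exponential vs linear coupling.** β is a *relative* sensitivity and the
  estimator normalises by window-mean GPP. Exponential growth makes that
  normalisation self-consistent: the window OLS slope is
  $\overline{GPP}_w\,\beta_{true}(centre)/10^4$ up to second order, so the
  trajectory and its trend are recovered without the systematic drift an
  additive-growth world would impose. The `"linear"` coupling mode
  ($G_0(1+F_t)$) exists because, at constant sensitivity, its noise-free
  output interpolates the regression model exactly — the raw generating
  coefficients are then recovered to machine precision, which is the
  sharpest possible regression diagnostic.
* **Confounder strength.** The VPD/Tmax terms shift the window-mean GPP
  slowly, which the normalisation converts into a spurious trend component
  of roughly $\beta\,(|c_1|\gamma_{VPD} + |c_2|\gamma_{Tmax})/G_0$ per year
  (γ = driver trend). The defaults ($c_1 = -6$ gC m⁻² yr⁻¹ hPa⁻¹ ≈ 0.5% of
  baseline GPP per hPa, $c_2 = -1.5$ per °C) keep this below 5% of the
  injected sensitivity trend, as the generator's recovery contract
  requires; the residual bias is visible in the noise-free recovery check
  (−0.0475 vs −0.05) and stays inside its ±10% tolerance.
* **Deterministic interannual variability.** Incommensurate sine terms
  (periods 7.3, 3.7, 5.1 years, per-pixel phases) give the meteorological
  fields ENSO-like variability that keeps the regression design full-rank
  even at zero noise. They are part of the stated world, not noise: the
  noise dials only add Gaussian perturbations on top.

All randomness flows from one master seed through per-variable substreams
(seed combined with a variable-name hash), so an identical config
reproduces every cube bit for bit regardless of generation order.
`generate_attribution_scenario()` builds windowed driver anomalies scaled
to unit sample sd with coefficients equal to the target shares, so the
noise-free recovered contributions equal the generating shares *exactly*;
"share" here means the |coef|·sd fraction that the standardized-coefficient
scheme estimates, which is the only construction under which the recovery
target is well defined.

What the generator does **not** emulate: the spatial texture and
autocorrelation of real satellite GPP, monthly phenology (the monthly
disaggregator simply replicates annual values), observational error
structure in the reanalyses, and any feedback of β onto the drivers. A
green recovery test therefore establishes that the estimator is correct
*for the assumed data-generating process*, not that real-world β trends of
any particular magnitude would be recovered — the published multi-decadal
trend and contribution values require the real satellite/reanalysis/CMIP6
archives, which are out of scope here.

## I/O and determinism

No NetCDF bindings are available in the supported environment, so gridded
I/O uses a plain-text format carrying the same CF-style metadata (variable,
units, lat/lon/year coordinates, optional month axis), written at `%.17g`
so round trips are bit-exact. Scenario ground truth is written to
`truth_*`-prefixed files that the driver reader deliberately ignores — a
pipeline cannot accidentally consume its own oracle. Pipeline outputs embed
a hash of the scientific configuration (excluding the output path) plus the
seed and package version, so mixing artifacts from different configurations
is detectable, and reruns are byte-identical.

## Known limitations

* Per-pixel β trends from 20 overlapping windows are strongly
  autocorrelated; their nominal p-values overstate significance. Use the
  across-seed spread for inference on synthetic data, and treat
  significance masks on real data as descriptive.
* The β normalisation by window-mean GPP means units-free β is only as
  stable as window GPP itself; pixels with near-zero mean GPP give
  unstable β_rel (masked when GPP is exactly zero, large otherwise).
* The attribution scheme partitions |coef|·sd shares; it is not a variance
  decomposition (no LMG/Shapley), and correlated drivers share credit
  according to their partial coefficients.
* Nearest-neighbour regridding uses a plain lat/lon Euclidean metric, as in
  the analysis it mirrors; near the poles this under-weights longitudinal
  proximity. No conservative regridding is provided.
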