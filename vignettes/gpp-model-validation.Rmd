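---
title: "Validating daily GPP models at flux towers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating daily GPP models at flux towers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gppval)
```

## What the package does

`gppval` is a site-scale validation pipeline for daily gross primary
production (GPP). It couples five pieces:

1. a **process-based forward model** — Farquhar C3 / Collatz C4 leaf
   photosynthesis scaled to the canopy through a single big leaf;
2. a **satellite-style light-use-efficiency (LUE) model** driven by NDVI,
   PAR, air temperature and the Bowen ratio;
3. **flux partitioning** that turns tower net ecosystem exchange (NEE)
   into "observed" GPP via a nighttime-fitted respiration law;
4. **Bayesian inversion** of the maximum carboxylation rate Vcmax by
   Metropolis–Hastings sampling, with per-plant-functional-type pooling;
5. a **validation layer** (R², RMSE, relative predictive error, biome
   aggregation, censuses, paired tests, toy global upscaling).

Because the real multi-site tower archive is not redistributable, the
package also ships a seeded synthetic-site generator with known truth, and
a packaged fixture of published per-site validation statistics (62 sites,
two models) on which all aggregate reproduction tests run.

## The forward photosynthesis model

For C3 leaves the gross rate is the minimum of three capacities
(mol CO₂ m⁻² s⁻¹):

$$J_E = \alpha_3\, Q_p\, \frac{c_i - \Gamma^*}{c_i + 2\Gamma^*},\qquad
  J_C = V_m\, \frac{c_i - \Gamma^*}{c_i + K_c(1 + O_2/K_o)},\qquad
  J_S = r_{tpu} V_m,$$

with $A = \min(J_E, J_C, J_S)$, floored at zero below the compensation
point $\Gamma^* = O_2 / (2\tau)$. For C4 leaves the three capacities are
$\alpha_4 Q_p$, $V_m$, and $k\,c_i$ (the low-CO₂ initial slope). $V_m$,
$K_c$, $K_o$ and $\tau$ follow single-Q10 responses
$x(T) = x_{25}\,Q_{10}^{(T-25)/10}$, with $Q_{10,\tau} < 1$ so the
compensation point rises with temperature.

**Defaults and why.** The published description of the model names its
lineage but prints neither kinetic constants nor quantum efficiencies, so
the defaults here are the community-standard values of that lineage
(α₃ = 0.060, α₄ = 0.050, Kc₂₅ = 1.5×10⁻⁴, Ko₂₅ = 0.25, τ₂₅ = 4500,
Q10 of 2.0/2.1/1.2/0.57, J_S = V_m/2.2, k = 0.7 mol m⁻² s⁻¹). Every one is
a `photo_params()` knob; none is asserted as a measured value. The
per-PFT Vcmax₂₅ defaults and the 1–300 µmol inversion range come from the
packaged nine-PFT catalogue (`load_pft_catalog()`).

**Deliberate simplifications.** Intercellular CO₂ is a fixed ratio of
ambient (0.7 for C3, 0.4 for C4) instead of a stomatal-conductance
closure; leaf temperature is the daily mean air temperature; the canopy is
one big leaf absorbing $1 - e^{-k\,\mathrm{LAI}}$ of incident PAR
(extinction k = 0.5); no nitrogen gradient, no energy balance, no sunlit /
shaded split. Colimitation is a hard minimum by default because that is
how the model family states it; a quadratic-smoothing mode (two coupling
coefficients, 0.97 and 0.99) is available but off by default.

**Units.** Driver files store PAR as a daily total (mol quanta m⁻² day⁻¹);
the forward model spreads it uniformly over the astronomical daylength,
integrates the leaf rate back over that daylength, and converts with
12.011 g C mol⁻¹.

## The light-use-efficiency model

$$\mathrm{GPP} = \varepsilon_{max}\cdot f\mathrm{PAR}\cdot
  \mathrm{PAR}\cdot \min(T_s, W_s)$$

with `fPAR = clamp(1.24·NDVI − 0.168, 0, 1)`, a quadratic
cardinal-temperature scalar $T_s$ (zero at 0 and 40 °C, one at 20.33 °C),
and the evaporative fraction $W_s = LE/(LE+H)$ — the inverse-Bowen-ratio
moisture scalar. The source description states the model's assumptions and
four drivers but not its coefficients, so the functional forms follow the
cited LUE-model family and every coefficient is a `lue_params()` argument.
Whether stresses combine by minimum or product is not stated either;
minimum is the default (matching that family), product is an option.
`eps_max` defaults to 0.465 g C mol⁻¹ quanta (≈ 2.14 g C MJ⁻¹) and can be
recalibrated in closed form by `fit_eps_max()`, since the model is linear
in it. Days with `LE + H ≤ 0` have undefined moisture stress and propagate
`NA` rather than a fabricated value.

## Flux partitioning

Daily "observed" GPP is daytime respiration minus daytime NEE:
$\mathrm{GPP} = R_{eco,day} - \mathrm{NEE}_{day}$ (NEE negative under
uptake). $R_{eco}$ extrapolates a Lloyd–Taylor law
$R(T) = R_{ref}\exp\!\big(E_0 (\tfrac{1}{T_{ref}-T_0} -
\tfrac{1}{T-T_0})\big)$ fitted by `nls` to nighttime NEE, with the
standard constants $T_{ref} = 15$ °C, $T_0 = -46.02$ °C. Nighttime NEE is
normalized from a per-night integral to a full-day-equivalent rate using
the astronomical night fraction before fitting; daytime and nighttime
temperatures are approximated by $(T_{avg}+T_{max})/2$ and
$(T_{avg}+T_{min})/2$. One fit per site replaces the moving-window
temperature-sensitivity estimation of the full tower-processing
algorithm — a documented simplification, not a claimed equivalence.
Partitioned GPP is floored at zero and the flooring count reported.

## Vcmax inversion

The posterior combines a uniform prior on the catalogue range
[1, 300] µmol m⁻² s⁻¹ with an iid Gaussian likelihood of observed daily
GPP around the forward model (sd = `likelihood_sd`, default
1 g C m⁻² day⁻¹ — the tower-processing description cites no likelihood, so
this is the package's choice, config-exposed). Sampling is random-walk
Metropolis–Hastings, 10000 samples by default with a 1000-sample burn-in.
The proposal sd starts at 5% of the prior range and, because the
posterior under two years of daily data is far narrower than that, is
adapted every 100 burn-in iterations toward a 20–50% acceptance band and
then frozen — adaptation confined to burn-in keeps the post-burn-in kernel
fixed and valid. The point estimate is the **posterior mode**: the center
of the most populated 1-µmol histogram bin of the post-burn-in samples
(ties break toward the bin with higher mean log posterior), matching the
highest-frequency rule and the catalogue's printed precision. Site optima
are pooled into the per-PFT scheme by arithmetic mean, with a one-way
ANOVA across PFTs; the ANOVA decomposition is written out so the
degenerate all-equal case reports F = 0 rather than 0/0.

Only Vcmax is inverted; everything else stays at PFT defaults. For speed
the forward model exposes a closure with all Vcmax-independent per-day
quantities precomputed, so a 10000-sample chain on a 730-day site costs
about a second in pure R; an independent grid search
(`grid_posterior_max()`, 0.25-µmol resolution) cross-checks every sampled
mode in the tests.

## The synthetic world

`generate_site()` emulates what the pipeline needs from a tower site, not
any particular climate:

* **Meteorology** — daily temperature as a latitude-dependent sinusoid
  (annual mean 27 − 0.38·|lat| °C, amplitude 0.32·|lat| + 1 °C, peak day
  200 in the north) plus Gaussian noise (sd 1.5 °C); PAR from the
  daylength cycle times a random cloud reduction; humidity, precipitation
  and a latent/sensible energy split with a seasonal evaporative fraction.
* **NDVI/LAI** — 8-day cadence tracking smoothed temperature, with a
  configurable fraction of points flagged unreliable and biased low, the
  way cloud-contaminated retrievals are.
* **Fluxes** — GPP truth is the package's own forward model at a known
  true Vcmax; respiration is Lloyd–Taylor with known (R_ref = 2, E₀ = 200);
  observed GPP adds Gaussian noise (default sd 0.5 g C m⁻² day⁻¹ — a free
  knob; the tower archive states only an annual uncertainty bound, no
  daily error model). Daytime NEE uses the *same* noise draw
  (NEE_day = R_day − GPP_obs), so the observable a perfect partitioner
  recovers is exactly `gpp_obs`; with independent draws the partitioning
  error would be inflated by irreducible observation noise that no
  algorithm can remove.

What a green test therefore establishes: the partitioner's
respiration-extrapolation error and the inversion's parameter recovery
under a self-consistent world. What it does not establish: robustness to
the structure of real tower data (u*-filtering artefacts, gap patterns,
storage fluxes, half-hourly dynamics, site-specific phenology), and it
cannot reproduce the published per-site statistics, whose raw inputs are
unpublished — those enter only through the packaged published table.

## Numerical choices and degenerate inputs

* Gap filling is linear interpolation between nearest reliable neighbours
  (nearest-value extension at the ends), idempotent by construction; an
  all-flagged series is an error, and any non-best quality flag counts as
  fillable (the flag-class mapping is not published; the rule is logged).
* Sub-compensation-point CO₂ yields zero gross photosynthesis, never
  negative; polar-night days yield zero GPP.
* A respiration fit with (near-)constant nighttime temperature is refused
  as unidentifiable rather than returned with a wild E₀.
* R² is the squared Pearson correlation (the scatterplot convention used
  when a model "explains x% of the variation"); `1 − SSE/SST` is available
  behind `r2_method = "ss"`. The published text does not define which was
  used; the Pearson form reproduces the printed biome means.
* Aggregation is computed at full precision and rounded to two decimals
  only for reporting; censuses use strict inequalities.
* Paired comparisons with zero-variance differences report a signed
  infinite t with a notice instead of erroring.

## Known limitations

No real satellite/reanalysis ingestion, no soil water or phenology
dynamics, no multi-parameter inversion, no convergence diagnostics beyond
acceptance rate and the trace, and the global "upscaling" is a unit
demonstration on toy grids. The published global means (107.50, 109.39,
123.97 Pg C yr⁻¹) enter as a packaged summary table; the 16.5 Pg C yr⁻¹
difference between parameter schemes is recomputed from that table, not
from a global run.
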