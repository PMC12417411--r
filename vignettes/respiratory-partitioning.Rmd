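---
title: "Partitioning leaf respiration in the light from dual-oxygen CO2-response curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning leaf respiration in the light from dual-oxygen CO2-response curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(co2resp)
```

## The problem

A C3 leaf in the light releases CO2 through two concurrent pathways:
photorespiration ($R_p$, the glycolate pathway downstream of Rubisco
oxygenation) and mitochondrial ("day") respiration ($R_d$). Standard
gas-exchange measurements only see their sum with assimilation, and the
respiration intercept of a fitted CO2-response curve is in fact the total
respiration in the light, $R_L = R_p + R_d$ — frequently mislabelled as
photorespiration alone. `co2resp` implements a measurement-plus-model
workflow that separates the components and quantifies how each responds to
ambient CO2 ($C_a$).

## The partitioning scheme

Three identities drive everything. At matched CO2 and light,

$$R_p = P_{n,2\%} - P_{n,21\%},$$

because 2% O2 suppresses Rubisco oxygenation while leaving carboxylation
and mitochondrial metabolism essentially intact; at $C_a = 0$ and
saturating light the 21% O2 net rate is $-R_L$ and the 2% O2 net rate is
$-R_d$, so the subtraction yields $R_L - R_d$. Across the CO2 staircase the
recovery/inhibition ratio of photorespiratory CO2 is

$$\rho_i = \frac{R_{p,\max} - R_{p,i}}{R_{p,\max}},$$

read as a *recovery* ratio below the CO2 level of peak photorespiration
(the fraction of respired CO2 re-fixed by the adjacent chloroplast) and as
an *inhibition* ratio above it (competitive suppression of oxygenation by
CO2). Because mitochondrially respired CO2 originates in the same cellular
neighbourhood, it is assumed recycled and inhibited with the same
efficiency, giving the day respiration from the dark rate $R_n$:

$$R_{d,i} = R_{n,i}\,(1 - \rho_i).$$

`build_respiration_series()` applies the chain per replicate and CO2
level: $R_p$ from the paired light curves, $\rho$ from the replicate-mean
$R_p$ series (no interpolation between measured CO2 levels), $R_d$ from the
dark series, and $R_L$ read directly off the 21% O2 curve where the leaf is
a net CO2 source, otherwise reconstructed as $R_p + R_d$. Sign convention:
net rates $P_n$ are signed (negative = net efflux); all respiratory fluxes
are positive magnitudes. $R_{p,\max}$ is the measured series maximum, not a
fitted-curve vertex, with ties broken to the lowest CO2 level. Negative
per-replicate $R_p$ values, which arise under noise near the peak, are
retained in averages (clamping would bias them) and listed in a QC
attribute. The dark series measured at 21% O2 feeds the $R_d$ calculation
by default — O2 level has no significant effect on the dark rate — with
`rn_source = "2"` as the alternative.

## The CO2-response models and their fitting

Four model forms are supported; each has a respiration intercept equal to
minus the model value at zero CO2, which is the quantity compared with the
measured fluxes.

* Rectangular hyperbola $P_n = \alpha P_{n\max} C/(\alpha C + P_{n\max}) - R_p$
  and Michaelis–Menten $P_n = P_{n\max} C/(C + K) - R_p$; the two are one
  model under $K = P_{n\max}/\alpha$ (a package test holds them to within
  $10^{-12}$ of each other).
* Modified rectangular hyperbola
  $P_n = a(1 - bC)/(1 + cC)\,C - R_p$, which admits an optimum and a
  decline and tracks measured respiration intercepts most closely on
  A/$C_a$ curves.
* Farquhar-type biochemical model
  $P_n = \min\{w_c, w_j, w_p\}(1 - \Gamma^*/C_i) - R_d$. The sub-rates use
  the standard formulations ($w_c$ Rubisco-limited, $w_j$
  RuBP-regeneration-limited, $w_p = 3\,TPU$). The compensation factor is
  the conventional $1 - \Gamma^*/C_i$; the photorespiratory compensation
  point is stored under its usual name $\Gamma^*$.

**Fixed kinetic constants.** $K_c = 270$ μmol mol⁻¹, $K_o = 165$ mmol
mol⁻¹, $O = 210$ (21% O2) or $20$ (2% O2) mmol mol⁻¹ and $\Gamma^* = 37$
μmol mol⁻¹ are held constant (configurable through `fvcb_params()` /
`fvcb_constants()`) rather than fitted. With only 12 points per curve,
freeing them alongside $V_{c\max}$, $J$, $TPU$ and $R_d$ would destroy
identifiability; fixing them is the standard practice for single-curve
fits. No temperature response of the constants is modelled.

**Optimizer.** `fit_co2_response()` minimizes the residual sum of squares
with `minpack.lm::nls.lm` under box constraints (all rate parameters
$\ge 0$; for the modified hyperbola additionally $b < 1/C_{\max}$ so the
curve stays valid over the data range). Bounds prevent the negative-rate
local minima that plain unconstrained Levenberg–Marquardt finds on short
curves. The non-smooth minimum inside the biochemical model is handled by
multi-start rather than by pre-assigning limitation states: the heuristic
start (`initial_guess()`: intercept read off the lowest-CO2 point, initial
slope off the two lowest points, saturation off the maximum) plus seven
log-normal perturbations of it, seeded deterministically from a hash of the
curve data so results are reproducible without touching the caller's RNG.
The candidate with the smallest SSR wins; $R^2 = 1 - SSR/SS_{tot}$ about
the observed mean, unadjusted. Curves with fewer than 5 usable points are
refused; for the biochemical model, points with CO2 at or below 1 μmol
mol⁻¹ are excluded since the compensation factor divides by $C_i$.
Replicates are fitted one at a time and the fitted parameters averaged
(mean ± SD) rather than pooled, matching how replicated curve experiments
are normally summarized.

**A/$C_a$ vs A/$C_i$.** The same functional forms are fitted against
either axis; the biochemical model fitted against $C_a$ simply substitutes
$C_a$ for $C_i$. `deviation_reduction()` and `compare_fitted_measured()`
quantify the accuracy gain of the A/$C_a$ axis as
$(\Delta_{C_i} - \Delta_{C_a})/\Delta_{C_i} \times 100$ with
$\Delta = |\text{fitted} - \text{measured}|$, undefined (reported `NA`)
when $\Delta_{C_i} = 0$.

## CO2 trends

$R_p(C_a)$ and $R_d(C_a)$ are unimodal; $R_n(C_a)$ declines roughly
linearly. `fit_trend()` fits ordinary least squares on a raw polynomial
basis — degree 2 by default, the minimal unimodal form, configurable —
and locates the extremum from the derivative's real roots inside the data
range. Regressions use replicate means, mirroring figure-level analysis;
at least degree + 2 points are required so a residual degree of freedom
remains. `peak_ca()` reports the grid CO2 level of the maximal mean (ties
to the lowest level) next to the smoothed extremum, flagging monotone
series.

## The synthetic generator

`sim_config()` / `simulate_gas_exchange()` emulate the measurement design
the pipeline assumes: the 12-level $C_a$ staircase (0–1200 μmol mol⁻¹),
light (PAR 2000 μmol m⁻² s⁻¹) and dark curves at 21% and 2% O2, $n = 5$
replicates. Truth profiles per species:

* $R_p(C_a)$: a quadratic anchored at its zero-CO2 value with vertex at
  the species' peak CO2 — wheat 4.923 → 12.307 peaking at 600, bean
  4.686 → 11.673 peaking at 1000 (μmol m⁻² s⁻¹; μmol mol⁻¹), magnitudes
  matching the observed ranges.
* $R_n(C_a)$: linear between its endpoints (wheat 3.862 → 1.453, bean
  4.040 → 1.210), identical at both O2 levels.
* $R_d(C_a) = R_n(C_a)\,R_p(C_a)/R_{p,\max}$ — the same recycling relation
  the pipeline inverts. This is a deliberate design choice: the measured
  day respiration is *defined* through that relation, so defining the
  generator's truth any other way would make the generator and the
  analysis mutually inconsistent and the closure property meaningless.
  With the default wheat profiles the implied $R_d$ peaks at 400 μmol
  mol⁻¹, as observed; a limitation is that the bean $R_d$ peak implied by
  this construction sits near 400 rather than the low value (~200)
  reported for field-grown bean, because the linear $R_n$ decline is not
  steep enough at low CO2 to move the product's vertex further down.
* Gross assimilation: a modified-rectangular-hyperbola shape (no
  respiration term) with defaults (wheat $a = 0.10$, $b = 3\times10^{-4}$,
  $c = 1.2\times10^{-3}$; bean $0.09$, $3\times10^{-4}$,
  $1.5\times10^{-3}$) giving realistic assimilation magnitudes
  (~20–30 μmol m⁻² s⁻¹ at high CO2) comfortably above the respiratory
  fluxes. The light-curve signals are $P_{n,21\%} = G - R_p - R_d$ and
  $P_{n,2\%} = G - R_d$, dark $P_n = -R_n$, so the partitioning identities
  hold exactly before noise.
* $C_i = 0.75\,C_a$, a fixed ratio: no stomatal model is simulated, but a
  fixed ratio suffices to exercise the A/$C_a$ vs A/$C_i$ fitting
  difference. Noise is homoscedastic Gaussian, default SD 0.3 μmol m⁻²
  s⁻¹, consistent with replicate SDs of a few tenths typical of
  cuvette-based systems; replicates are independent (no between-replicate
  correlation structure is emulated). Simulation is bit-reproducible given
  the seed.

What passing tests on these data do and do not show: they verify that the
estimators invert the generating process exactly (noiseless closure to
$10^{-10}$) and stably under noise, not that real leaves obey the model —
real data add stomatal dynamics, heteroscedastic and drifting instrument
error, leaf-to-leaf correlation, and possible failure of the equal-recycling
assumption behind the $R_d$ relation.

## Numerical choices and degenerate inputs

Compensation points and realized maxima (`derived_quantities()`) come from
a dense grid scan with `uniroot`/`optimize` refinement rather than closed
forms. Flat curves fall back to fixed default starts instead of erroring.
An all-zero photorespiration series has no defined recovery profile and is
refused. A `recovery_inhibition()` profile labels the peak itself as the
end of the recovery phase, so phases always partition the grid into a
prefix and a suffix. CSVs are written with 17 significant digits so
read–write round trips are exact.

## Problem sizes

The test suite fits each model family on 12-point curves (noiseless
recovery to $10^{-4}$ relative), runs a 200-replicate Monte Carlo check of
the modified-hyperbola respiration estimator (median within 5% of truth at
noise SD 0.3), and a 100-seed coverage check that replicate-mean $R_p$
stays within $3\sigma/\sqrt{n}$ of truth at ≥95% of grid points — sizes
chosen to make the statistical assertions stable while keeping the suite
quick.

## Known limitations

No mesophyll conductance ($C_c$-based) variants, no temperature or light
response, no isotopic recycling estimation, no stomatal model, no ANOVA
layer. The equal-recycling assumption linking $R_d$ to $R_n$ is a modelling
hypothesis, not a measurement; where it fails, $R_d$ estimates inherit the
error.
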