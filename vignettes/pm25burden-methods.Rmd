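---
title: "Methods: projecting PM2.5 exposure and attributable mortality under combined pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting PM2.5 exposure and attributable mortality under combined pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pm25burden)
```

## The problem

Long-term exposure to fine particulate matter (PM2.5) causes premature
mortality through chronic obstructive pulmonary disease (COPD), ischaemic
heart disease (IHD), stroke and lung cancer (LC).  How that burden evolves
over a century depends on four coupled drivers: emission-driven changes in
ambient concentration, climate-change-induced meteorology (ventilation,
washout, mixing depth), demographic change (total population and its age
structure), and the epidemiologic transition (background death rates
falling as economies grow).  `pm25burden` implements a desk-scale,
fully-testable version of a national assessment of this kind: exposure is
projected on a 0.5° grid from a multi-model ensemble under two emission
pathways (a stabilization analogue, `rcp45`, and a high-emission analogue,
`rcp85`), and converted into attributable deaths under the demographic and
economic drivers of five shared socioeconomic pathways (SSP1–SSP5).

## Exposure model

**Speciated estimate (approach 1).**  Each ensemble member's PM2.5 is the
mass sum

$$\mathrm{PM}_{2.5} = \mathrm{BC} + \mathrm{OA} + \mathrm{SO_4} +
\mathrm{NH_4} + 0.25\,\mathrm{SS} + 0.1\,\mathrm{dust},$$

with ammonium inferred as $\mathrm{NH_4} = 36\,\mathrm{SO_4}/96$ (all
sulphate assumed to be ammonium sulphate) and fixed fine-size fractions for
sea salt and dust.  Members that report only one of primary/secondary
organic aerosol have the missing component imputed cell-wise with the
reference member's POA/SOA ratio (`pm25_from_species()`).

**Conversion-factor estimate (approach 2).**  A per-cell conversion factor
$\eta = \mathrm{PM}_{2.5}/\mathrm{AOD}$ is computed once from the
baseline-period satellite-style fields (`compute_eta()`) and applied,
unchanged, to each member's projected aerosol optical depth.  Because
$\eta$ encodes baseline meteorology, this estimate responds to emissions
only; the cell-wise difference approach 2 − approach 1
(`meteorology_delta()`) therefore isolates the meteorological contribution.

**Bias-robust scaling.**  Climate models misestimate absolute aerosol loads
substantially, so absolute member fields are never used directly.  For each
member and pentad the *relative* change from that member's own baseline
window is applied back onto the satellite-derived baseline surface
(`project_pentad()`):

$$\mathrm{PM}^{proj} = \mathrm{PM}^{sat}_{bl}\left(1 +
\frac{\mathrm{PM}^{mod}_{p} - \mathrm{PM}^{mod}_{bl}}
{\mathrm{PM}^{mod}_{bl}}\right).$$

Member projections are summarised cell-wise into mean and 1σ spread
(`ensemble_summarize()`); consecutive pentads are averaged into decades.
The relative change is computed per member and then summarised — the σ
field needs member-level values; a central estimate built from the
ensemble-mean relative change is available via
`relative_change = "ensemble_mean"` and coincides with the default when
member noise vanishes.

## Health-impact model

Relative risk follows the integrated exposure–response (IER) form

$$RR = 1 + \alpha\left[1 - e^{-\gamma\,\Delta\mathrm{PM}^{\delta}}\right],
\qquad \Delta\mathrm{PM} = \max(\mathrm{PM}_{2.5} - c_0,\, 0),$$

with counterfactual $c_0 = 5.8\ \mu g\,m^{-3}$, so $RR \in [1, 1+\alpha]$
and no excess risk is assigned below $c_0$.  IHD and stroke carry one
$(\alpha,\gamma,\delta)$ triple per 5-year age bin (25–29 … 80+); COPD and
LC carry a single triple.  Because published coefficient look-up tables are
not redistributable here, the package ships an *illustrative,
non-authoritative* default set (`default_ier_coefficients()`) whose only
guaranteed properties are the structural ones (positivity, age-resolution,
saturation); substantive work should supply a vetted CSV via
`read_ier_csv()`.

Attributable deaths per cell use the attributable fraction:
$\Delta M = y \cdot \frac{RR-1}{RR} \cdot P$, linear in both the baseline
rate $y$ and the exposed adult population $P$.  Cells inherit the baseline
mortality rate of their administrative zone, adjusted to the decade's GDP
with an anchored power law $y(G) = a\,G^{-b}$ ($b = 0$ for LC, which shows
no GDP relation).  The decade GDP applies the mean of two GDP-PPP
projections relative to a common reference year, uniformly across zones.
Exposed population uses the first year of each decade; age-specific
populations are the cell total times national age fractions.

**Uncertainty bands.**  The default (joint) mode re-evaluates the entire
chain at mean ± 1σ exposure with the GDP–mortality coefficients shifted
∓/± one standard error in the direction that lowers/raises the predicted
rate; monotonicity of the chain in both inputs guarantees
low ≤ central ≤ high.  A quadrature mode that perturbs the two sources
separately and combines their effects in quadrature is provided because
the joint convention is not the only defensible reading.

## Scenario matrix and sensitivity decomposition

Two emission pathways × five SSPs give ten combinations; the high-emission
pathway is inconsistent with the green-growth SSP1 storyline, so that cell
is refused (not silently skipped) and nine feasible cells remain
(`scenario_matrix()`, `run_matrix()`).

Four counterfactual studies decompose the change from the baseline-period
reference burden (baseline exposure, population and rates):

* **SA1 (demography)** — decade population and age structure, everything
  else at baseline.  Linear in $P$: uniform doubling gives exactly +100%
  of the reference.
* **SA2 (epidemiology)** — decade GDP drives $y$, everything else at
  baseline.  Linear in $y$: uniform halving gives exactly −50%.
* **SA3 (meteorology)** — burden from the approach-2 exposure minus burden
  from approach 1, with population and rates following the decade in both
  arms; positive values are deaths averted by meteorological change.
* **SA4 (policy caps)** — exposure scaled uniformly so the national mean
  meets the staged air-quality interim targets (35, 25, 15 µg m⁻³ in the
  near, distant and far future); the scaling is parameter-free and lands
  on the target exactly.  A "reduce exceeding cells first" allocation
  would need an ordering parameter with no empirical anchor and is not
  implemented.

## What the synthetic generator emulates — and what it does not

All inputs are produced by a seeded generator (`synthetic_config()` and
`generate_*`); identical (seed, config) yields bit-identical bundles.  The
generator plants exactly the structure the pipeline is designed to detect:

* a smooth positive baseline field with a Gaussian high-exposure hotspot,
  rescaled to a 34.5 µg m⁻³ national mean;
* a 13-member ensemble whose speciated totals follow
  baseline × trend × (1 + met) and whose AOD follows baseline_AOD × trend,
  with shared member noise — so the approach difference recovers the
  planted meteorological term by construction;
* the default stabilization-pathway meteorology effect ramps from −7% to
  −17% across the 18 pentads; the high-emission pathway's term is weakly
  negative early, positive mid-century and negative again in the final
  decade;
* organic-aerosol reporting gaps (member 1 reports POA and SOA, members
  2–3 only POA, members 4–5 only SOA, the rest combined OA);
* five population pathways of which only the SSP3 analogue grows to 2100
  (the others peak mid-century), geometric age structures that flatten
  over time (aging), strictly rising GDP trajectories, and zone mortality
  rates consistent with the anchored power law.

Member noise is multiplicative lognormal, independent across members and
pentads, spatially correlated through a Gaussian smoothing kernel.  The
correlation length is a free knob, not a calibrated quantity — real
inter-model disagreement has structured, seasonally varying covariance
that a single length scale cannot represent.  Other realism limits:
"states" are a rectangular 4×4 partition, the land mask is procedural, the
species shares are spatially constant, and the IER defaults are
illustrative.  Passing tests therefore demonstrate the correctness of the
*method* (algebraic identities, planted-signal recovery, conservation,
ordering), not the accuracy of any absolute national estimate; absolute
published values would require the real model archives, satellite baseline
and pathway databases.

## Numerical choices

* National means are cos(latitude)-weighted over land cells.
* Downscaling is bilinear interpolation of cell-centre values (exact on
  linear fields; nearest-neighbour available); targets outside the coarse
  hull are refused.
* Projected cells driven below zero are floored at zero and counted
  (attribute `n_floored`); a zero model-baseline cell is an error because
  the relative change is undefined.
* A zero reference denominator in POA/SOA imputation sets the imputed
  component to zero and counts the cells (`n_zero_ratio`).
* Age fractions must sum to 1 within 1e-9; capping tolerances are relative
  1e-9; serialization uses 17 significant digits for bit-exact round trips.
* Pentad calendar is fixed at 2011–2015 … 2096–2100; decade *d* averages
  pentads (2d−1, 2d); the decade population is the first-year population.

## Problem sizes used in the checks

The shipped tests and the acceptance script run the full pipeline at the
default study scale (62 × 60 half-degree grid, 13 members, 18 pentads, two
pathways — about 12 s end to end) and use reduced domains (10 × 10 or
6 × 6 cells, 2–5 members) for oracle comparisons and property sweeps,
where brute-force per-cell loops are feasible.  These sizes are the
package's own choice of test geometry; every identity they check is
resolution-independent.
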