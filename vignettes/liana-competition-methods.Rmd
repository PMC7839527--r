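---
title: "Disentangling water and light competition between lianas and trees: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangling water and light competition between lianas and trees: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lianacomp)
```

Lianas are structural parasites: instead of building self-supporting
stems they climb host trees, spend the saved carbon on leaves and roots,
and compete with their hosts both above ground (for light, by shading the
canopy they just overtopped) and below ground (for soil water, through
shallow but dense fine-root systems). Whether light or water dominates
this competition is hard to measure: it requires replicated liana-removal
experiments at ecosystem scale. `lianacomp` approaches the question *in
silico*: it couples a deliberately compact cohort/patch vegetation
simulator with a liana plant functional type (PFT) to a Bayesian trait
meta-analysis and a variance-based uncertainty workflow, and asks which
group of liana parameters — water-related or light-related — generates
most of the spread in simulated liana productivity.

This vignette documents the models, their assumptions, the tunable
constants and the numerical choices. It is the authoritative description
of what the package computes; every number shown is produced by the code
at build time.

## 1. The demographic simulator

### State and structure

The simulated forest is a set of *patches* (areas sharing a disturbance
age, each with its own soil column and area weight summing to one across
the site) holding *cohorts*: groups of plants of one PFT and similar
diameter at breast height (DBH, cm), tracked as stem densities per m²
rather than individuals. Everything is spatially implicit. Four PFTs are
used: one liana and early-, mid- and late-successional evergreen tropical
trees classified by wood density (cut points 0.53 and 0.71 g cm⁻³,
configurable). Tree parameters are held fixed throughout; only the 32
liana parameters vary in the uncertainty analysis.

### Allometry and the climbing rule

Biomass pools follow power laws in DBH: leaf `Bl = b1Bl·DBH^b2Bl`, stem
`Bs = b1Bs·DBH^b2Bs`, fine roots `Br = q·Bl` (kg C per plant), leaf area
`SLA·Bl`. Height uses a saturating form
`h = h_max·(1 − exp(−b1Ht·(DBH + ΔDBH)^b2Ht))`; the functional form is a
design choice (the source model's exact form is internal to it), with
`h_max` = 35 m for trees and 40 m for lianas so that the liana curve can
always represent a canopy-topping climber. `ΔDBH` is the liana-specific
offset that shifts the height allometry: at initialization every liana at
or above `DBH_threshold` = 3 cm is assumed to have reached the canopy and
is placed `h_offset` (default 0.5 m, not a published value) above the
tallest tree of its patch, and `ΔDBH` records the difference between the
allometric DBH at that height and the actual DBH. During growth, lianas
first grow in diameter, compute a potential height from the shifted
allometry, and are then capped at the tallest tree plus `h_offset`,
updating `ΔDBH` — the two-step climbing rule. The cap is applied at the
monthly growth step and at initialization (not continuously), and liana
leaf area is placed at the cohort's capped height, which is the mechanism
by which climbing confers a light advantage. Rooting depth is
`−b1Rd·h^b2Rd` (m): under the data-constrained coefficients a 16 m canopy
liana roots to `r rooting_depth(16, liana_parameters())` m — the data
confine liana roots to the first metre of soil, versus
`r round(rooting_depth(16, liana_parameters("prior-median")), 2)` m under
the prior medians.

### Water: hydraulics and the soil bucket

Plant water state is two storage compartments (stem, leaf) with
capacitances `C_wood·2·Bs` and `C_leaf·2·Bl` (kg water per m of water
potential; the factor 2 converts carbon to biomass), potentials in m H₂O.
Flows are `q₁ = G_sr(ψ_soil − ψ_stem)` from soil to stem and
`q₂ = G_sl(ψ_stem − ψ_leaf − h)` to the leaves, with the gravitational
head equal to height. `G_sl` combines the Weibull vulnerability curve
`K(ψ) = K_max·exp(−ln2·(ψ/P50)^K_exp)` — anchored so `K(0) = K_max` and
`K(P50) = K_max/2` — with a sapwood cross-section proxy derived from stem
biomass and wood density (sapwood fraction 0.3); `G_sr` additionally
carries a saturating fine-root-area factor `SRA·Br/(SRA·Br + 50 m²)` and
a pathway ratio `c_sr = 2`. These three constants are packaged in
`hydro_constants()` and documented there; they were chosen once so that
an unstressed canopy tree transpires of order 10⁻⁴ kg s⁻¹ per m² of
leaf, and are not part of the uncertainty analysis.

The update over a sub-step is an exact backward-Euler solve of the
linearized two-compartment system (conductances frozen at the entry stem
potential). This is unconditionally stable and — because extraction,
transpiration and storage change are computed from the same solved
potentials — conserves water *identically*, which is why the budget
residuals in the tests sit at 10⁻¹³ rather than merely below the 10⁻⁶
requirement. Transpiration demand is `1.6·g_s·D` per leaf area with
Ball–Berry conductance `g_s = gs_min + m·max(A_net,0)·rh/ca`
(`gs_min` = 0.01 mol m⁻² s⁻¹, CO₂ fixed at 370 ppm) and `D` the
leaf-to-air vapour mole-fraction deficit (Magnus formula, standard
pressure). Realized transpiration is capped so the leaf potential never
falls below the turgor loss point; below `leaf_TLP` both assimilation
and stomatal conductance are cut to zero (a hard-cutoff reading of the
turgor-loss parameter; the source model's exact use is not public).

The soil is an eight-layer bucket (interfaces at
0.05/0.15/0.3/0.5/0.75/1/2/4/8 m) with Clapp–Hornberger retention
`ψ = ψ_sat(θ/θ_sat)^{−b}` and clay-loam defaults (θ_sat 0.45, θ_res
0.08, ψ_sat −0.35 m, b 6.5). Fine roots place a fraction `1 − root_beta`
uniformly over `[0, rooting depth]` and `root_beta` below it, matching
the parameter's definition without inventing a profile shape. Each
cohort extracts water from layers in proportion to its root fraction,
throttled when a layer cannot supply the aggregate demand; infiltration
fills layers top-down with the excess leaving as drainage (no explicit
inter-layer redistribution — adequate for wet tropical profiles, a known
simplification); canopy interception evaporates a fixed 10% of daily
rain; soil evaporation from the top layer is shaded by canopy LAI.

### Light, carbon and demography

Light competition is a Beer–Lambert profile (`k` = 0.5) through the
height-ordered cohorts, each cohort seeing the PAR attenuated by the
leaf area above it plus half its own. Gross assimilation is the
co-limited hyperbola `A_g = f_sw·α·PAR·V_m/(α·PAR + V_m)` with the
stomatal drought factor `f_sw = 1/(1 + (ψ_leaf/ψ_b)^c)` (equal to ½ at
`stoma_psi_b`); no temperature kinetics are applied (`V_m0` is used
as-is) and phenology is evergreen. Leaf dark respiration
`dark_respiration·V_m` is paid day and night.

Days integrate physiology (6 daytime and 2 nighttime hydraulic
sub-steps, 12 h daylength); months close the carbon balance
`CB = GPP − R_leaf − R_root − R_growth` with
`R_growth = growth_respiration·max(CB_pre, 0)`. Tissue turnover
`(leaf_turnover·Bl + root_turnover·Br)/12` is paid first — from storage
when the balance is negative, then by shedding leaf and fine-root mass.
Of the positive remainder, a `reproduction_carbon` fraction goes to a
per-patch recruit pool (spawning 1-cm cohorts above 0.02 kg C m⁻²) and
the rest drives diameter growth by inverting the total-biomass allometry
with vectorized Newton iterations — carbon-exact rather than a
first-order derivative step, which is what lets the monthly cohort
closure test demand 10⁻⁶ relative error. Mortality combines a
density-independent rate `mort3` with a carbon-starvation logistic
`mort1/(1 + exp(mort2·c̄b))`, where `c̄b` is the trailing 12-month mean
of the carbon-balance-to-turnover ratio clamped to [0, 1] (1 when the
balance covers maintenance, 0 under starvation); `mort1` = 1 yr⁻¹ is a
structural constant (only the shape `mort2` is a trait). Cohorts below
10⁻⁸ stems m⁻² are dropped. Patch fusion is not performed: tests rely
on deterministic patch identity.

The no-liana scenario (`remove_lianas()`) deletes liana cohorts from the
initial state and changes nothing else.

## 2. Trait priors and the meta-analysis

The packaged prior table carries, for each of the 32 liana parameters, a
distribution family with two constants interpreted as uniform(min, max),
normal(mean, sd), lognormal(meanlog, sdlog), gamma(shape, rate),
beta(shape1, shape2) or weibull(shape, scale) — this parameterization
reproduces the tabulated prior medians for 27 of the 32 rows at printed
precision. Four traits that are physically negative (`P50`,
`stoma_psi_b`, `leaf_TLP`, `b1Rd`) are stored positive and multiplied by
−1 at use; on the use scale the p-quantile of the negated variable is
minus the (1−p)-quantile. The two capacitance priors are specified on a
unit system 10³ above the tabulated medians; a per-row `scale` factor of
10⁻³ is applied after sampling, which reconciles them exactly. Three
rows (`b1Bl`, `V_m0`, `SLA`) print medians inconsistent with their
stated constants under any parameterization we found, and `mort2` prints
15.36 where the gamma(1.2, rate 0.058) median is 15.31; these four are
documented here, excluded from the exact-median tests, and their
tabulated medians are used directly in the packaged parameter sets.

The meta-analysis is a two-level random-effects model: observed trait
means `y_i ~ N(θ_study(i), s_i²)`, study effects `θ_j ~ N(β₀, τ²)`, the
packaged prior on the across-study mean `β₀`, and a weakly-informative
inverse-gamma(0.001, 0.001) prior on τ². The exact mixed-model structure
behind the published posteriors is not public; study-level random
intercepts are the canonical choice for tables of study means and site
identity is retained only as metadata. Sampling is
Metropolis-within-Gibbs — conjugate updates for `θ_j` and τ², a
random-walk Metropolis step for `β₀` so that any prior family can sit on
the grand mean — with 4 chains × 5000 draws and 1000 burn-in by default,
split-R̂ reported and a convergence warning recorded in the posterior's
provenance above 1.1. Missing standard errors are imputed as the prior
sd divided by √n when n is known, else the prior sd, and flagged. With
no observations the posterior *is* the prior, sampled. Parameter
uncertainty is summarized as `CV = sqrt(Var[β₀])/|median(β₀)|`. For the
allometric coefficient pairs, where too few studies exist for the
hierarchical model, `fit_allometric_prior()` builds data-informed priors
from an OLS fit on log–log axes, drawing coefficient pairs from the
estimated bivariate-normal sampling distribution.

## 3. Sensitivity, variance decomposition and ensembles

Each trait is varied one at a time around its median at ±1, 2, 3 SD,
interpreted as normal-CDF probability levels
Φ(z), z ∈ {−3,…,3} = {0.00135, …, 0.99865}, pushed through the trait's
own quantile function — analytic for priors, empirical for posterior
draw sets. This convention (rather than additive shifts in raw units)
keeps the design meaningful for the skewed and bounded families in the
prior table. The seven model responses are interpolated by a monotone
Hermite cubic spline (`splinefun(method = "monoH.FC")`) with linear
extrapolation beyond the outer design points, so posterior tails beyond
the design span do not acquire spurious curvature. Elasticity is
`ε = g′(β̄)·β̄/g(β̄)` — the local power-law exponent — evaluated from
the interpolant's derivative, hence recovered only approximately
(slope-limited finite differences) when the response is genuinely
curved.

The decomposition transforms each trait's posterior draws through its
spline: `Var_p = Var[g_p(β₀_p)]`, `tot.var = Σ_p Var_p`,
`rel.var_p = Var_p/tot.var`; draws (not an analytic transform) are used
because that is how the posterior is propagated in the source workflow's
illustration. Relative variances are aggregated over the packaged
classification of each trait into competition type (water/light, with
unclassified traits reported separately), organ and process; shares over
each partition sum to one by construction and are tested to 10⁻¹².
Traits are sampled independently in ensembles (no covariance structure
is published); `ensemble()` summarizes run spread by empirical medians
and a 95% envelope, and `ci_spread_ratio()` quantifies the contraction
bought by the meta-analysis.

## 4. The synthetic study conditions

The generators encode the study conditions as defaults. Two site
templates: a drier, strongly seasonal, liana-rich site (2640 ± 94 mm
yr⁻¹; January–March below 60 mm, April below 100 mm; 1428.9 lianas ha⁻¹
at DBH ≥ 1 cm; 416 trees ha⁻¹ and 26.7 m² ha⁻¹ at DBH ≥ 10 cm) and a
wetter one with a short autumn dry season (3088 ± 117 mm; September–
October below 60 mm, August and November below 100 mm; 126.3 lianas
ha⁻¹ at DBH ≥ 2 cm; 319.4 trees ha⁻¹, 19.2 m² ha⁻¹). Rainfall is built
from monthly targets — 45 mm in strong-dry months, 80 mm in dry months,
wet months sharing the annual draw with a smooth seasonal shape and a
120 mm floor — realized as wet/dry day sequences with gamma amounts
rescaled to exact monthly totals, so the dry-season classification of
generated series is deterministic. PAR, temperature and humidity carry
mild seasonality anti-correlated with rain. Tree DBHs come from a
truncated power law on [10, 150] cm whose exponent is solved so density
and basal area match jointly (two-moment matching), placed at stratified
quantiles so site-level moments are tight at desk-scale stem counts.
Patch-level liana loading is a lognormal multiplier (sd-log 1.1,
normalized to mean one across patches), spanning near-liana-free to
heavily infested patches. Trait datasets are generated from a known
hierarchical truth for calibration experiments.

What the generators do *not* emulate: real stem maps, species identity,
measured meteorology, interannual drought anomalies, or the covariance
between liana load and stand structure. Passing tests therefore
demonstrate internal correctness and the direction of the simulated
mechanisms — not quantitative agreement with any real forest.

## 5. Problem sizes, defaults and limitations

The packaged analyses use 10 patches of 400 m² over 5 simulated years
for the conservation, climbing and liana-removal suites, 4 patches over
1 year per design point for the sensitivity runs, 25 seeded replicates
for the meta-analysis calibration and ensembles of 20–250 members —
sizes we consider sufficient for the properties being tested, chosen as
the package's own desk-scale defaults. A full run writes monthly
per-PFT GPP, NPP, autotrophic respiration, transpiration, LAI and AGB
plus site water terms, and carries three closure diagnostics (maximum
water and carbon residuals, climbing-cap violations) that the test
suite asserts against.

Known limitations, deliberate and otherwise: one canopy light band and
a single daily radiation value; no leaf energy balance or temperature
kinetics; instantaneous xylem refilling (the vulnerability curve is
evaluated at the current potential with no hysteresis); no treefall or
patch-generating disturbance; no nutrient cycling; no deciduous
phenology; no mechanical damage by lianas to their hosts; growth,
mortality and recruitment operate monthly, so sub-monthly drought
mortality is smoothed. The one-at-a-time design makes sensitivities
dependent on where the medians sit, which is intrinsic to the method;
global designs are out of scope. At desk scale the absolute liana
shares and growth reductions are smaller than ecosystem-scale estimates
with real forcing; the package's claims are the conservation laws, the
analytic reproductions and the directions of the mechanisms, which is
what the acceptance suite asserts.
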