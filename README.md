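# lianacomp

Lianas (woody vines) climb host trees instead of building self-supporting
stems, then compete with them for light from above and for soil water from
below. Which resource dominates that competition — and when, and where — is
nearly impossible to measure directly, because it requires ecosystem-scale
liana-removal experiments. `lianacomp` addresses the question numerically,
for ecosystem modellers and plant ecologists: it implements a desk-scale
cohort/patch vegetation simulator with a climbing liana plant functional
type (PFT) and mechanistic plant hydraulics, a Bayesian trait
meta-analysis that constrains the 32 liana parameters from observation
tables, and a variance-based uncertainty workflow that attributes the
spread of simulated liana productivity to water-related versus
light-related parameters.

## The models in brief

**Simulator.** Cohorts (density, DBH, biomass pools, water potentials)
live in patches with layered soil columns. Liana height is restricted by
the climbing rule: a liana's potential height from its ΔDBH-shifted
allometry is capped at the tallest tree of its patch plus a small offset
*h*offset; every liana above DBH = 3 cm starts canopy-topping. Light is a
Beer–Lambert profile through the height-ordered canopy; water transport is
a two-compartment (stem/leaf capacitance) scheme with the Weibull
vulnerability curve *K*(ψ) = *K*max·exp(−ln2·(ψ/P50)^*K*exp), Ball–Berry
stomatal conductance with drought down-regulation
*f* = 1/(1 + (ψleaf/ψb)^c), and a hard turgor-loss cutoff. Monthly
demography closes each cohort's carbon balance exactly (allocation,
turnover, reproduction, diameter growth by inverting the biomass
allometry, carbon-starvation mortality, recruitment).

**Meta-analysis.** For each trait *p*, observed means feed a two-level
random-effects model with the packaged prior on the across-study mean
β₀ₚ, sampled by Metropolis-within-Gibbs; uncertainty is summarized as
CVₚ = √Var[β₀ₚ]/|β̄₀ₚ|.

**Uncertainty.** Each trait is varied one at a time at ±1, 2, 3 SD
(normal-CDF probability levels through the trait's own quantile
function); responses are fitted with a monotone Hermite cubic spline
*g*ₚ; elasticity is εₚ = *g*ₚ′(β̄)·β̄/*g*ₚ(β̄); partial variances
rel.varₚ = Var[*g*ₚ(β₀ₚ)]/Σₚ Var[*g*ₚ(β₀ₚ)] are aggregated into
water-, light-related and unclassified parameter classes, and
Monte-Carlo ensembles compare prior- against posterior-constrained
predictive spread.

Synthetic generators emulate the two study conditions — a drier,
strongly seasonal, liana-rich site and a wetter site with a short dry
season and few lianas — so the whole chain runs without external data.
See the methods vignette (`vignettes/liana-competition-methods.Rmd`) for
assumptions, constants and limitations.

## Worked example

```r
library(lianacomp)

## constrain the liana stem conductivity K_max from (synthetic) trait data
tab  <- liana_prior_table()
pr   <- tab$prior[[which(tab$name == "K_max")]]
obs  <- generate_trait_dataset("K_max", true_mean = 0.1, between_sd = 0.02,
                               within_sd = 0.01, n_studies = 13,
                               obs_per_study = 5, seed = 42)
post <- run_meta_analysis(pr, obs, mcmc_settings(seed = 1))
post
#> <trait_posterior> K_max (meta-analysis): median 0.1098, cv 0.0735, 16000 draws
post$cv / coefficient_of_variation(pr)
#> [1] 0.06

## simulate a liana-infested seasonally dry stand for two years
tpl    <- site_template("bci", n_patches = 4)
forest <- synthetic_forest(tpl, seed = 1)
met    <- generate_met(tpl, years = 2, seed = 2)
sim    <- run_simulation(forest, met, years = 2, seed = 1)
sim
#> <liana_sim> 2 years, 24 monthly records
#>   mean ecosystem GPP 3.08 kg_C m-2 yr-1; liana share 15.2%
#>   max water residual 4.23e-13, max carbon residual 2.65e-11
summary(sim)
#>     pft gpp_kgC_m2_yr npp_kgC_m2_yr  mean_lai final_agb
#> 1 early     0.5678458     0.2922165 0.9818030  5.901705
#> 2  late     0.5223299     0.3104241 0.9271458 12.315090
#> 3 liana     0.4667331     0.2214095 0.3374618  1.484422
#> 4   mid     1.5228695     0.8859629 2.1935620 24.838615
```

Reading the output: the posterior median of *K*max lands near the known
truth (0.1 kg m⁻¹ s⁻¹ m⁻¹) used to generate the observations, and the
meta-analysis contracts its coefficient of variation to 6% of the
prior's. The simulated stand photosynthesizes at a realistic tropical
rate (≈3 kg C m⁻² yr⁻¹), lianas contribute ~15% of it while holding
only ~1.5 of ~44 kg C m⁻² of aboveground biomass — the structural-
parasite signature — and the water and carbon budgets close to machine
precision (the `max ... residual` diagnostics).

From there, `remove_lianas()` gives the paired no-liana scenario,
`run_sensitivity()`/`variance_decomposition()` attribute output variance
to traits and competition classes, `dry_season_mask()` and
`select_young_patches()` carve out the seasonal and stand-age scenarios,
and `ensemble()` propagates prior or posterior parameter uncertainty.

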