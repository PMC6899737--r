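# thermofr

Temperature-dependent functional responses, metabolic scaling, and the
energetic efficiency of stream predators.

## What it does

Warming raises both the feeding rates and the metabolic demands of
ectotherm predators; whether a population can persist depends on which
rises faster. `thermofr` implements the complete estimation chain for
benthic stream predators feeding on blackfly larvae (Simuliidae) across a
natural geothermal temperature gradient:

1. **Functional responses from prey-depletion trials.** Feeding over a
   24 h trial without prey replacement follows the depletion ODE
   `dN/dt = -cN^h/(1 + cbN^h) - mN`, with attack coefficient `c`, handling
   time `b`, Hill exponent `h` (type I/II/III) and background mortality
   `m`, each scaled to temperature by a Boltzmann–Arrhenius factor
   `exp(E (T - T0) / (k T T0))`. Survivor counts are binomial around the
   integrated ODE; parameters are estimated by maximum likelihood
   (`fit_mortality()` from controls, then `fit_fr()`), and all 55
   combinations of parameter-sharing structures across experimental
   datasets are compared by BIC (`fit_fr_zoo()`, `select_by_bic()`).
2. **Metabolic scaling from respirometry.** `fit_metabolism()` converts
   O₂ consumption to J/h and regresses `ln I` on the Arrhenius abscissa
   `x = (T - T0)/(kTT0)` and `ln` dry mass, so coefficients are activation
   energies (eV) and allometric exponents; candidates (with/without mass,
   interaction, quadratic temperature) are ranked by BIC, and
   `thermal_optimum()` extracts the vertex of a quadratic fit.
3. **Energetic efficiency.** `energetic_efficiency()` combines both fits
   per stream: `y = ω(T) · F_E / I`, with `F_E` the energy feeding rate at
   the stream's prey density and `ω` a logistic-Arrhenius assimilation
   efficiency. `y < 1` marks streams where feeding cannot meet metabolic
   demand; `efficiency_profiles()` smooths `y` against temperature and
   predator abundance.

Calibrated synthetic-data generators (`simulate_fr_experiment()`,
`simulate_respirometry()`, `simulate_streams()`) emulate the study designs
so every stage is testable without any data download, and
`run_pipeline()` orchestrates all stages and writes plain CSV/JSON
artifacts.

## Worked example

```r
library(thermofr)

# simulate the two-dataset caddisfly experiment from its published truth
trials <- simulate_fr_experiment(fr_design_potamophylax(),
                                 fr_truth_potamophylax(), seed = 5)
fit <- fit_fr(trials, type = "II", c_structure = "separate_sharedE",
              b_structure = "shared")
summary(fit)
#> Type II functional response (c: separate_sharedE, b: shared)
#> Estimates are on the natural scale; SE and z on the fitting scale
#> (log for intercepts, so z = ln(estimate)/SE; linear for energies):
#>
#>  parameter   dataset estimate     se       z         p
#>         c0 Field2015   2.4170 0.6965  1.2671 2.051e-01
#>         c0   Lab2015   0.7597 0.3965 -0.6931 4.882e-01
#>        E_c  Combined   0.2847 0.4150  0.6860 4.927e-01
#>         b0  Combined   0.5830 0.1191 -4.5286 5.937e-06
#>
#> logLik = -438.186, k = 4, n = 254 arenas, BIC = 898.522
#> 10/10 optimizer starts converged
```

The attack coefficient differs between the laboratory and field settings
but shares one activation energy across them (here recovered as
0.28 ± 0.42 eV against a generating value of 0.229 — at these handling
times feeding is saturated over most of the density ladder, so a single
experiment pins the shared handling time sharply but the attack activation
energy only loosely). The shared handling time of 0.58 days/individual
corresponds to a maximum feeding rate of about 1.7 prey/day in every
setting.

```r
# metabolic scaling and thermal optimum of the quadratic respiration model
rec <- simulate_respirometry(truth = metabolic_truth_potamophylax(),
                             sigma_ln = 0.4, seed = 5)
met <- fit_metabolism(rec)
attr(thermal_optimum(1.072, quad = -0.339), "celsius")
#> [1] 21.36299

# per-stream energetic efficiency across a 4-25 C survey gradient
streams <- simulate_streams(n_streams = 14, seed = 5)
eff <- energetic_efficiency(streams, fit, met, dataset = "Field2015")
print(efficiency_profiles(eff))
#> Energetic-efficiency smoothers over 14 streams
#>   y ~ temperature (gam): F = 387.87, r2 = 0.992
#>   y ~ abundance (gam): F = 13.27, r2 = 0.767
```

Efficiency declines steeply with stream temperature because the
caddisfly's metabolic activation energy (~1.07 eV) far exceeds that of
its attack coefficient (~0.23 eV); streams whose efficiency falls below
the break-even line `y = 1` are flagged in the returned table.

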