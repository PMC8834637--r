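# storekin

Storage-stability kinetics for carotenoids in beverages: one-step
(global) Arrhenius fitting of degradation curves, joint confidence
regions for the rate parameters, light-dose accounting for illuminated
storage, and a synthetic-data generator that emulates a realistic
shelf-life study.

## The scientific problem

Carotenoids give yellow-orange fruit and vegetable beverages their colour
and are lost during storage, mainly by oxidation; light accelerates the
loss. A storage study follows the concentration `Ct` (ug per g beverage)
of each all-trans carotenoid at several temperatures, against storage
time in days (dark storage) or against cumulative light dose in
megalux-hours (illuminated storage). The questions the package answers:

1. **Which kinetic law?** Zero order (`Ct = C0 - kT*t`), first order
   (`Ct = C0*exp(-kT*t)`), or fractional conversion
   (`Ct = Cinf + (C0 - Cinf)*exp(-kT*t)`, decay toward a plateau).
2. **How does the rate depend on temperature?** Through the Arrhenius
   relation `k(T) = kref * exp[(Ea/R)(1/Tref_K - 1/T_K)]` with
   `Tref = 25` degC, `R = 8.314` J/mol/K and `Ea` in kJ/mol. Fitting is
   *one-step*: all temperatures enter a single nonlinear least-squares
   problem, so `kref` and `Ea` are estimated directly with correct
   uncertainty propagation, rather than via per-temperature fits followed
   by an Arrhenius regression (that two-step route is still available as
   a diagnostic, `fit_two_step()`).
3. **How uncertain are the estimates, jointly?** Exact-SSQ joint
   confidence regions in the `(kref, Ea)` plane, with overlap tests to
   compare packaging materials or formulations.
4. **What does a chamber dose mean on the shelf?** Conversions between
   Mlux-h and retail days under an explicit lighting schedule, plus a
   Welch test for rate differences and ascorbic-acid/oxygen
   stoichiometry helpers.

## Worked example

Simulate a dark-storage study for beta-carotene (glass bottles, four
temperatures, duplicate extractions, 2% analytical noise), let the
package choose the kinetic law, and inspect the fit:

```r
library(storekin)

tab <- make_paper_fixture("dark", "glass",
                          noise = noise_spec(sd = 0.02, seed = 7),
                          carotenoids = "beta-carotene")

cmp <- select_model(tab)
cmp
#> <model_comparison> selected: fractional
#>        order p     SSQ     SEE  r2adj    runs_p
#> 1 fractional 4 0.02794 0.02318 0.9786 7.874e-01
#> 2      first 3 0.19752 0.06105 0.8517 1.204e-06
#> 3       zero 3 0.26204 0.07031 0.8033 1.224e-06

fit <- cmp$fits[[cmp$selected]]
fit
#> <kinfit> fractional-order, axis time_days, m = 56, p = 4
#>   C0    = 1.22468 +/- 0.0079
#>   Cinf  = 0.747292 +/- 0.00812
#>   kref  = 0.082577 +/- 0.00457
#>   Ea    = 15.6676 +/- 1.47
#>   SSQ = 0.0279366, SEE = 0.0231785, r2adj = 0.9786, runs p = 0.787

fit$k_by_temperature
#>   temperature_C          k          se
#> 1            10 0.05908024 0.003556702
#> 2            20 0.07413793 0.004076474
#> 3            35 0.10137689 0.006160122
#> 4            45 0.12286233 0.008656028
```

The generating truth was `C0 = 1.22`, `Cinf = 0.732`, `kref = 0.075`
per day, `Ea = 15.13` kJ/mol — recovered within one to two standard
errors, and the misspecified first- and zero-order fits are flagged both
by their larger SEE and by runs-test p-values near 1e-6 (systematic
residual sign patterns).

A 90% joint confidence region for `(kref, Ea)`, profiling out the
concentration parameters:

```r
reg <- jcr_region(fit, phi = 0.10, nuisance_mode = "profiled")
reg
#> <jcr_region> 90% region, p = 4, m = 56, SSQ_min = 0.02794, threshold = 0.03236
#>   estimate: kref = 0.08258, Ea = 15.67 kJ/mol (per_day, profiled nuisance)
#>   1 contour polygon(s), 1204 of 6561 grid points inside
```

Regions for two packagings can be compared with `regions_overlap()`.
For illuminated storage the same machinery runs on the dose axis, and
`light_schedule()` maps results to shelf days — a 600-lux shelf lit 12
h/day accumulates 0.0072 Mlux-h per day, so 180 retail days correspond
to about 1.3 Mlux-h:

```r
sched <- light_schedule(600, 12)
dose_from_days(180, sched)
#> [1] 1.296
```

A YAML-driven end-to-end pipeline (`run_pipeline()`) and a command-line
interface (`inst/cli/storekin.R`, with `validate`, `simulate`, `fit`,
`convert`, `compare` and `run` subcommands) wrap these steps for batch
use.

## Documentation

The methods vignette (`vignettes/carotenoid-storage-kinetics.Rmd`)
describes the models and their assumptions, the numerical choices
(multi-start bounded Levenberg-Marquardt, tie-breaking rules, the
confidence-region threshold convention and its measured coverage), the
synthetic generator's realism and limits, and known limitations.
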