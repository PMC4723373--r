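# immunokin

Saturable-binding compartmental kinetics of radiolabeled antibodies in
antigen-expressing tumors.

## The problem

Serial immunoPET of a radiolabeled monoclonal antibody yields
time-activity curves (TACs, in %ID/g) for the tumor and for blood.  At
therapeutic antibody masses the tumor antigen pool saturates, so uptake
per unit dose falls — a linear compartment model extrapolated from
tracer-dose data gets high-dose predictions qualitatively wrong.
`immunokin` implements a three-compartment model with a non-linear,
saturable association step for exactly this setting: estimating binding,
internalization and efflux kinetics from tracer-dose TACs and
extrapolating tumor exposure and the targeting index to therapy-scale
doses.  Intended users are preclinical imaging and radioimmunotherapy
modelers.

## The model

Plasma `q1(t)` (measured heart TAC or analytic curve) forces two tumor
states, surface-bound `q2` and internalized `q3` (µM):

    dq2/dt = k_a ([Ag_total] − [Ag−Ab]) q1(t) − k_int q2
    dq3/dt = k_int q2 − k_efflux q3
    C_tumor = q2 + q3 + 0.08 q1

with occupancy [Ag−Ab] = q2 + q3 (or interpolated from measured tumor
activity during fitting).  Parameters: `k_a` (M⁻¹h⁻¹), `ag_total` (µM),
`k_int`, `k_efflux` (h⁻¹), fixed 8% tumor blood fraction.  A linear
comparator replaces the saturable term by `k21_lin q1(t)`.  Fitting is
Poisson-weighted (w = 1/y) bounded least squares with a seeded
Latin-hypercube multistart.

## Worked example

```r
library(immunokin)

# a synthetic dose-ranging study with known ground truth
cfg   <- synthetic_config(seed = 1, noise_cv = 0, doses_ug = 240)
study <- generate_study(cfg)
a     <- study$animals[[1]]

fit <- fit_kinetics(a$tumor_tac, biexponential_input(cfg), a$injection,
                    fit_config(occupancy_mode = "state_driven", seed = 1))
fit
#> Compartmental fit (nonlinear variant)
#>          estimate       se
#> k_a       2.0e+05 1.95e-01
#> ag_total  1.3e+00 1.18e-06
#> k_int     2.0e-01 6.12e-07
#> k_efflux  9.0e-02 9.17e-08
#> RMSE: 8.41e-05 %ID/g; objective: 4.656e-14; ...
```

The estimates reproduce the generating parameters (`k_a` 2e5 M⁻¹h⁻¹,
`ag_total` 1.3 µM, `k_int` 0.2 h⁻¹, `k_efflux` 0.09 h⁻¹) to ~1e-5
relative at zero noise.  Extrapolating the low-dose fit across doses:

```r
tab <- predict_dose_series(params_zirconium_like(),
                           c(60, 180, 240, 1000, 2000),
                           biexponential_input(cfg))
round(tab$targeting_index, 2)
#> [1] 8.59 6.17 5.37 1.95 1.07
```

The saturable model predicts a targeting index that falls with dose
(here ~8-fold from 60 to 2000 µg); the linear comparator predicts a
dose-constant index — the operational difference that matters for
choosing a therapy dose from tracer-dose imaging.  Molecule-scale
turnover from a simulated trajectory:

```r
inp_uM <- input_function(function(t)
  pidg_to_molar(biexponential_input(cfg)(t), a$injection), unit = "uM")
tr <- simulate_trajectory(params_iodine_like(), inp_uM,
                          seq(0, 96, by = 0.25), injection = a$injection)
internalization_flux(tr, params_iodine_like())   # molecules g^-1 h^-1
#> [1] 2.535568e+13
per_cell_turnover(1.2e13, cells_per_gram = 1e8, sites_per_cell = 6e5)
#> $molecules_per_cell_per_h
#> [1] 120000
#> $site_fraction_per_h
#> [1] 0.2
```

A flux of 1.2e13 molecules g⁻¹h⁻¹ is 1.2e5 molecules per cell per hour,
i.e. 20% of a 600,000-site surface pool internalized per hour.

See `vignettes/saturable-immunokinetics.Rmd` for the model assumptions,
identifiability analysis and all numerical choices.

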