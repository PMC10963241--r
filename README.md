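# surfcrowd

Kinetics of enzymes that depolymerize **solid** substrates — PET
hydrolases on plastic film being the motivating case — under **surface
crowding**. At low loading, more enzyme means more product; past an
optimum, additional enzyme packs the surface, pushes adsorbed molecules
into crowded, less active configurations, and the macroscopic rate
*falls*. Conventional interfacial rate laws (inverse Michaelis–Menten)
are monotone in enzyme and cannot capture this inhibition effect.

The package is for enzymologists and modelers who have (or simulate)
initial-rate grids over enzyme × substrate loadings plus adsorption
isotherms, and want mechanistic parameters out of them.

## The model

With total enzyme `E_T` (nM), substrate surface concentration `N_0`
(cm²/L), site density `Γ` (nmol/cm², so `Γ·N_0` is in nM), and
adsorption equilibrium constant `K_a` (1/nM), the adsorbed complex is
the physical root of the binding quadratic
`K_a (E_T − EN)(ΓN_0 − EN) = EN`. Coverage is `θ = EN/(ΓN_0)`.
Adsorbed enzyme partitions between uncrowded and crowded states with
equilibrium constant `K_c`:

    EN_uc = EN (1 − θ) / (K_c θ + 1 − θ),    EN_c = EN − EN_uc

and the macroscopic rate is

    dP/dt = k_cat,uc · EN_uc + k_cat,c · EN_c = k_app(θ) · EN,
    k_app(θ) = k_cat,uc (1 − θ + c K_c θ) / (K_c θ + 1 − θ),
    c = k_cat,c / k_cat,uc ≤ 1.

Five parameters: `K_a, Γ, K_c, k_cat,uc, k_cat,c`. At `K_c = 1`,
`k_cat,c → 0` the law reduces to the classical adjacent-free-site
depolymerase model.

Estimation is two-step, in log-parameter space, with multi-start
bounded optimization: `(K_a, Γ)` by maximum likelihood from the
adsorption isotherm, then all five by maximum a posteriori on the rate
grid with the step-1 estimates (and their Gauss–Newton covariance) as
the prior. `compare_models()` contrasts the crowding model with the
inverse Michaelis–Menten law by BIC on identical weighting. A
surface-geometry module converts adsorbed amounts to areal densities
and nearest-neighbor distances (Poisson closed form `1/(2√λ)` plus
seeded Monte Carlo) and analyzes localization-microscopy coordinate
tables.

## Worked example

Simulate a 30 °C study from the wild-type reference parameters
(`K_a = 0.0290`, `Γ = 0.0291`, `K_c = 0.890`, `k_cat,uc = 0.445`,
`k_cat,c = 0.0588`) with 5% replicate noise, then run the two-step fit:

```r
library(surfcrowd)
wt <- petase_params("WT", "30C")

ads   <- generate_adsorption(wt, cv = 0.05, seed = 1)
prior <- as_prior(fit_adsorption(ads, N_0 = attr(ads, "N_0"), seed = 1))
kin   <- generate_kinetics(sim_config(wt, cv = 0.05), seed = 2)
fit   <- fit_kinetics(kin, prior, seed = 1)
fit
#> Fit (kinetics): objective 84.0005 over 64 starts (56% in best basin)
#>   parameter estimate   lower   upper
#> 1       K_a  0.02866 0.01604 0.05122
#> 2     Gamma  0.02973 0.01660 0.05322
#> 3       K_c  0.86076 0.22505 3.29214
#> 4  k_cat_uc  0.42746 0.36503 0.50055
#> 5   k_cat_c  0.05771 0.03355 0.09927
#> weighted SSR 83.2541 on 50 observations, BIC 45.05
```

All five generating values are recovered inside their 95% intervals.
The fitted surface has an interior productivity optimum, and local
sensitivities there rank site density above the uncrowded catalytic
constant, with crowding strength negative:

```r
opt <- optimal_loading(fit$params, N_0 = 500)
#> optimal loading: 59.0 nM, max rate 1.954 mA260/min
round(normalized_sensitivity(fit$params, opt$E_T_star, 500), 4)
#>      K_a    Gamma      K_c k_cat_uc  k_cat_c
#>  -0.0001   1.9545  -0.8014   1.6744   0.2800
compare_models(kin, prior, seed = 1)$delta_bic
#> [1] -155.4
```

The strongly negative ΔBIC (SC minus inverse MM) says the two extra
parameters of the crowding model are decisively supported on data that
contain an inhibition maximum. Sensitivity units are those of the rate
(mA260/min); `sensitivity_table()` adds a rate-normalized column.

Geometry, in one breath: 4 pmol of enzyme on both faces of a
0.25-inch film is `λ ≈ 0.038 /nm²`, i.e. ~5.1 nm even-grid spacing and
~2.56 nm mean nearest-neighbor distance for random placement —
molecule-scale packing, which is the physical case for crowding.

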