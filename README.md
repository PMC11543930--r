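# backflux

Thermodynamic reversibility of microbial catabolism leaves an isotopic
fingerprint: during net anaerobic oxidation of an n-alkane coupled to
sulfate reduction, a small carbon flux runs *backwards* from the CO2 pool
into the alkane pool.  In a closed incubation amended with
13C-bicarbonate, that back flux progressively enriches the residual
alkane in 13C.  `backflux` turns such labeling time series into a
quantitative estimate of the back flux, and models the thermodynamic
feasibility of the underlying catabolic pathway (anaerobic butane
oxidation, AOB, and its reverse).  It is aimed at geomicrobiologists and
biogeochemists working with alkane-oxidizing enrichment cultures or
designing isotope labeling experiments.

## The model

Two empirical curves summarise an incubation: first-order substrate decay
and logistic 13C enrichment,

    [Alk](t)  = c0 + (c1 - c0) exp(-lambda t)
    delta13C(t) = d0 + (d1 - d0) / (1 + exp(-k (t - d2)))

The net rate is `v = lambda ([Alk] - c0)`.  Writing `F_Alk` and `F_CO2`
for the 13C atom fractions of the two pools (the latter follows from
closed-system mass conservation of C and 13C) and `alpha+`, `alpha-` for
the kinetic fractionation factors of the forward and backward fluxes, the
isotope balance of the alkane pool gives the fractional back flux in
closed form:

    mu(t) = ( d[13C_Alk]/dt + n v alpha+ F_Alk )
            / ( n v ( alpha- F_CO2 - alpha+ F_Alk ) )

with `f- = mu n v` (CO2 -> alkane, carbon-atom basis) and
`f+ = (1 + mu) v`, so `v = f+ - f-/n`.  Uncertainty comes from sampling
the seven curve parameters with an affine-invariant ensemble MCMC
sampler (Goodman-Weare stretch move; 128 walkers x 5000 cycles by
default) and pushing every draw through the same pipeline.

On the thermodynamic side, the 17-reaction AOB pathway (butane
activation, butyl-CoM/butyryl-CoA conversion, beta-oxidation, oxidative
Wood-Ljungdahl, membrane electron transport) is solved for
quasi-equilibrium metabolite activities: each reaction is pinned at
`dG = 0`, or at `n_H * (-20) kJ/mol` where it couples to the proton
motive force, and one designated dissipation reaction closes the energy
balance as slack.  Feasibility requires all intermediates within
1 uM - 10 mM and non-positive dissipation.  Rayleigh fractionation
estimation (`rayleigh_alpha`) and the flux-force relation
`f-/f+ = exp(dG/RT)` complete the toolkit.

## Worked example

Simulate the default 98 atom% labeling experiment (6 mmol/L butane,
18 mmol/L DIC, 5% concentration noise, 1 permil delta-13C noise,
sampling every 10 d) and fit it with posterior bands:

```r
library(backflux)
cfg <- experiment_config(seed = 1)
sim <- simulate_experiment(cfg)
fit <- backflux(sim$data, mcmc = TRUE, seed = 1)
fit
#> Isotope mass-balance back-flux fit
#>   alkane decay: c0 = 0.08736, c1 = 5.842 mmol/L, lambda = 0.03844 /d
#>   enrichment:   d0 = -25.04, d1 = 79.87 permil, d2 = 79.73 d, k = 0.07989 /d
#>   peak back flux: mu = 0.00182 (1.82 permil of net rate) at t = 83.5 d
#>   95% band at peak: [1.56, 2.09] permil
```

The back flux is bell-shaped: it grows as the thermodynamic drive weakens
with substrate depletion, then collapses when net oxidation ceases.  Its
peak -- here 1.82 permil of the net AOB rate, with a 95% credible band of
[1.56, 2.09] permil -- quantifies how far the pathway runs in reverse.
`plot(fit)` draws the two fitted curves and the mu(t) band;
`summary(fit)` adds standard errors and MCMC diagnostics.

The pathway model answers the complementary question of whether the
catabolic machinery *can* run at these energies:

```r
m <- pathway_model(Ex = -0.22, xh2_x_ratio = 2)
catabolic_dg(m)                      # -127.40 kJ per mol butane
electron_ledger(m)$electrons_total   # 26
sol <- qe_solve(m, coupling_scheme(m, pmf = c("15" = 2, "16" = 2),
                                   dissipation = 11))
sol$feasible                         # FALSE: energy recovery alone
min(sol$activities)                  # 9.27e-23 mol/L -- intermediates collapse
```

Without proton-motive-force investment at the endergonic steps the
quasi-equilibrium intermediate pool falls far below 1 uM, i.e. the purely
energy-recovering pathway is kinetically unfeasible; `net_proton_search()`
enumerates proton stoichiometries over the coupling sites.

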