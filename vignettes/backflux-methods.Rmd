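---
title: "Methods: isotope mass-balance back flux and pathway thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope mass-balance back flux and pathway thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(backflux)
```

## The scientific problem

Anaerobic oxidation of butane (AOB) by archaeal-bacterial consortia is
thermodynamically reversible: while butane is oxidised to CO2 with
sulfate as the terminal acceptor, a small carbon flux runs from the CO2
pool back into the butane pool.  In a closed incubation whose dissolved
inorganic carbon (DIC) is 13C-labeled, that back flux transfers label
into the shrinking butane pool and raises its delta-13C far beyond what
kinetic fractionation of the forward flux alone could produce.  The
package quantifies the back flux from such time series and, separately,
asks whether the 17-step catabolic pathway is thermodynamically able to
sustain flux in either direction.

## The isotope mass balance

The balance of 13C in the alkane pool during an infinitesimal time step
receives label from the back flux (`f-`, carbon-atom basis) in
proportion to the CO2 pool's atom fraction `F_CO2`, and loses label with
the forward flux (`f+`, alkane basis) in proportion to the alkane's own
atom fraction `F_Alk`, each weighted by a kinetic fractionation factor:

$$\frac{d[^{13}C_{Alk}]}{dt} = n\,\mu v\,\alpha_- F_{CO_2}
  - n\,(1+\mu)\,v\,\alpha_+ F_{Alk},$$

where `n` is the number of carbons per alkane (4), `v` the net
consumption rate and `mu = f-/(n v)` the fractional back flux.  Two
empirical curves close the system: a three-parameter first-order decay
for the butane pool and a four-parameter logistic for its delta-13C.
Everything on the right-hand side then has a closed form, and solving
for `mu` gives the explicit estimator implemented in
`back_flux_extent()`.  `F_CO2` never needs to be measured: the closed
system conserves total carbon and total 13C, so it follows from the
initial pools.

Identifiability fails where the denominator
`n v (alpha- F_CO2 - alpha+ F_Alk)` vanishes -- at label crossover and
once net oxidation ceases.  Points where it falls below 1e-6 mmol C/L/d
(or `v` below the matching rate floor) are masked, never extrapolated.

### Parameters that matter

| parameter | meaning | unit | default |
|---|---|---|---|
| `alpha_plus`  | forward kinetic fractionation | -- | 0.9975 (epsilon = -2.5 permil) |
| `alpha_minus` | backward fractionation | -- | 1 (inaccessible; estimate robust over 0.90-1) |
| `n`           | carbons per alkane | -- | 4 |
| `alk0`, `dic0`| initial pools | mmol/L | 6, 18 |
| `atom13_dic0` | initial DIC label | atom fraction | 0.98 (study range 0.0112-0.98) |
| `tol`         | denominator mask | mmol C/L/d | 1e-6 |

`alpha_plus` is estimated from a natural-abundance incubation by the
logarithmic Rayleigh regression (`rayleigh_alpha()`); the default is the
package-wide anchor.  The free energy of the overall sulfate-coupled
process (`overall_delta_g()`) needs a standard value `dg0_overall`
supplied by the user -- the package deliberately ships no default, so
only free-energy *changes* along an incubation are asserted by the
tests, never absolute values.

## Bayesian inference

The seven curve parameters are sampled as two independent blocks --
(c0, c1, lambda) against the concentration series, (d0, d1, d2, k)
against delta-13C -- mirroring the two separate least-squares
sub-models.  Likelihoods are Gaussian with fixed scales: 5% of the mean
observed concentration, and 1 permil for delta-13C.  Priors are uniform
and wide (`default_priors()`): c0 in [0, alk0], c1 in [0.5, 2] x alk0,
lambda in [1e-4, 1] /d, d0 in [-60, 20] permil, d1 in [-60, 1000]
permil, d2 in [0, 2 t_max], k in [1e-3, 1] /d.

Sampling uses the affine-invariant stretch move (128 walkers x 5000
cycles, burn-in 2000, 1000 retained draws).  Two design choices deserve
comment:

* **Walker initialization.** Stretch-move proposals interpolate between
  ensemble members, so when no walker starts near a narrow posterior
  basin the ensemble contracts onto whatever likelihood ridge the best
  random draw happened to hit and the split-chain scale reduction
  stays far above 1.1.  With priors as wide as d1 in [-60, 1000] permil
  this is the typical outcome of prior-uniform starts.  The default
  (`init = "ball"`) therefore jitters the walkers around the
  least-squares estimate (2% relative scale, clipped to the prior
  support), the standard practice for this sampler family;
  `init = "prior"` remains available.  The initialization does not
  change the target distribution, only whether the sampler reaches it.
* **Fixed likelihood scales.** Because sigma is fixed rather than
  estimated, posterior width does not shrink to zero on noise-free data;
  the posterior median trajectory tracks the deterministic mu(t) but
  the credible band retains the width implied by the assumed sigma.
  Tests assert median tracking and band coverage, not band collapse.
  For the same reason, tightening only the delta-13C sigma narrows the
  peak band just down to the share contributed by the concentration
  block.

Convergence checks: split-chain R-hat < 1.1 for every parameter, and
integrated autocorrelation time (per-walker autocorrelations averaged,
Sokal window c = 5) times 50 no larger than the chain length.  The
burn-in default of 2000 cycles is the conservative of the two plausible
readings of the protocol (1000 is also defensible); both are arguments.

## The synthetic-data generator

The generator emulates the study's incubations: 6 mmol/L butane,
28 mmol/L sulfate (5 in the sulfate-limited variant), 18 mmol/L DIC at
one of five label levels, sampling every 10 d over 0-160 d,
multiplicative Gaussian noise of 5% on concentrations, additive 1 permil
on delta-13C with three technical replicates per time point, and sulfide
accumulating at 3.25 mol per mol butane consumed (26 electrons per
butane over 8 per sulfate), capped at the supplied sulfate.  The default
truth parameters (c0 = 0.1, c1 = 6 mmol/L, lambda = 0.04 /d; d0 = -25
permil, d2 = 80 d, k = 0.08 /d) are chosen once to satisfy the printed
anchors -- over 98% of the butane consumed by about 120 d, delta-13C
plateau near +80 permil at 98% label and near -15 permil at natural
abundance -- with the plateau `d1` interpolated linearly in the initial
label fraction between those two anchors.  The 10-d schedule is an
inference from the figure axes and is configurable.

Two modes share this configuration.  The *parametric* mode draws the
exact closed-form curves the estimator assumes -- useful for
inverse-consistency tests.  The *mechanistic* mode integrates the
two-pool isotope ODE with a known true back flux (deSolve/lsoda,
rtol 1e-9, atol 1e-12) and is the independent oracle: the estimator
never sees the ODE, only its sampled output.  One numerical subtlety:
the ODE carries isotopologue-resolved label shares
`alpha F / (1 + (alpha - 1) F)` rather than the linearised `alpha F` of
the balance equations, so that its zero-back-flux natural-abundance
limit reproduces closed-form Rayleigh distillation exactly; the
difference is O((1-alpha) F), about 1e-7 in absolute mu for the default
experiment, invisible at the 10% oracle-equivalence tolerance.  What
passing these tests shows is that the analytic pipeline inverts data
whose generating process matches its assumptions (first-order kinetics,
well-mixed closed pools, constant alphas); it does not validate those
assumptions for any real incubation, and the generator deliberately
omits headspace partitioning, pH-dependent DIC speciation and biomass
dynamics (a fixed assimilation fraction, default 0 and optionally 0.04,
is the only nod to growth).

## Quasi-equilibrium pathway thermodynamics

Each of the 17 reactions is pinned at a target free energy -- 0 at
equilibrium, `n_H * (-20) kJ/mol` at proton-motive-force (PMF) coupled
sites (positive `n_H`: protons translocated outward, energy conserved;
negative: protons invested) -- giving one linear equation per reaction
in the log activities of the 12 internal metabolites and the log
reduced/oxidised ratios of the four internal redox couples.  Free
carrier forms (HS-CoM, HS-CoB, CoA, H4MPT, MF) are boundary species at a
configurable 1e-3 mol/L, gas-phase butane and CO2 default to activity 1,
water to 1, and the external XH2/X ratio is an input; temperature is
298 K with R = 8.314e-3 kJ/mol/K and activities equal concentrations.
One designated dissipation reaction is excluded from the system and its
free energy recovered afterwards as the slack that closes the pathway
energy balance exactly (the closure is an identity of the construction
and is tested to 1e-6 kJ/mol).  The solver is QR-based with an explicit
rank check (undetermined species are named in the error) and a relative
residual tolerance of 1e-8; feasibility demands every solved metabolite
inside 1 uM - 10 mM (dimensionless ratios exempt) and non-positive
dissipation.

### What the solver shows about the oxidative pathway

Holding PMF coupling to the four default sites (butyl-CoM conversion,
F420H2 and ferredoxin oxidation, MQ-to-X transfer, dissipation at
methylene-H4MPT oxidation), the solve with energy recovery alone leaves
intermediates many orders of magnitude below 1 uM -- the pathway is
kinetically unfeasible without energy investment, which is the central
qualitative result the module reproduces.  Pushing further, no integer
proton assignment at those four sites yields a *fully* in-window
solution under the default boundary convention: equilibrium at both the
acetyl-CoA cleavage step (dG0' = +66.1 kJ/mol) and the formyl-MF
dehydrogenase step constrains the shared CO2/ferredoxin term
`ln a_CO2 + 2 ln r_Fd` from above and below incompatibly, independent of
the proton counts, the XH2/X ratio and the gas activities.
`net_proton_search()` therefore returns an empty table for the shipped
defaults, by design rather than by failure; schemes with additional
coupling or dissipation sites (any reaction index is accepted) or other
boundary conventions can be explored with the same machinery.  The
published concentration figures for this pathway evidently rest on an
activity convention that their text does not fully specify -- the same
reason the absolute catabolic free energies are not asserted anywhere in
the tests, while their spacing (exactly 13 RT ln 2 per doubling of the
carrier ratio) and the reversal antisymmetry are.

### Default coupling numbers

The per-site proton counts are declared inputs; the defaults (-1 at the
butyl-CoM conversion, +2 at each of the two recovery sites, -1 per
MQ-to-X step, dissipation at methylene-H4MPT oxidation; mirrored signs
and dissipation at acetyl-CoA synthesis for the reverse direction) are
an anchor for the search facility, not a claim about the organism.

## Numerical choices

* Nonlinear fits: Levenberg-Marquardt (`minpack.lm::nls.lm`) with
  analytic Jacobians, ftol = ptol = 1e-10; starting values from the
  documented recipes (ends of the series, log-linear or half-rise
  slopes).  A constant concentration series is an error (no decay to
  fit); a flat delta-13C series returns a fit flagged `degenerate`.
* Technical replicates are averaged per time point before fitting,
  matching the measurement protocol (n = 3 per sample).
* Trajectory masking as above; a fully masked trajectory is an error
  ("no identifiable back flux window").
* Seeds: every stochastic entry point takes a `seed` argument and
  restores the caller's RNG state; identical seeds give byte-identical
  datasets, draws and sweep tables.
* Problem sizes used by the shipped tests and the acceptance script:
  17-point schedules, mu(t) grids of 0.1-0.5 d, the full 128 x 5000
  MCMC protocol, and four-point oracle sweeps -- each chosen as the
  smallest size at which the corresponding check is stable.

## Sensitivity protocol

`sensitivity_sweep()` varies one factor at a time around the base
configuration -- alpha_plus by +/-0.0002 (its 95% confidence limits),
alpha_minus over {0.90, 0.95, 1}, the concentration error term over
{2.5, 5, 10}%, and the initial DIC pool by +/-10% -- and tabulates the
peak back flux with its relative deviation from the base cell.  The
sigma factor acts on the generator's noise in simulation mode and on the
likelihood in inference mode; these are deliberately separate switches.
Failed cells are recorded and skipped, and the sweep is reproducible
under a fixed seed.

## Known limitations

* The back-flux estimate inherits the empirical curves: dynamics that
  are not first-order-plus-logistic (diauxie, lags, pulsed feeding) bias
  mu(t) in ways the posterior band does not capture.
* alpha_minus is unidentifiable from a single labeling level and is
  fixed, not estimated; the sensitivity sweep bounds its influence.
* The quasi-equilibrium model is static: it screens feasibility windows
  and energy budgets but contains no rate laws, and its verdicts depend
  on the declared boundary convention as discussed above.
* Headspace/liquid partitioning and DIC speciation are upstream of every
  interface; all concentrations are liquid-equivalent mmol/L.
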