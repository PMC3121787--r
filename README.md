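# isoturn

Analysis tools for controlled **diet-switch stable-isotope experiments**:
isotopic incorporation kinetics with individual heterogeneity, diet–tissue
discrimination, and simulation-based evaluation of sampling designs.

The package is written for trophic ecologists and ecophysiologists who run
(or plan) feeding experiments in which animals equilibrated on one diet are
switched to another and tissues are sampled repeatedly — the emulated design
is a 40-individual arctic-fox experiment (balanced females/males and
adults/yearlings; 20 animals shifted from a terrestrial to a marine diet,
20 kept as controls; blood sampled on days 0, 4, 7, 11, 15, 19, 23, 28, 35,
55 and 70 after the shift).

## The model

Isotopic incorporation in a tissue after a diet switch is modelled as
single-pool first-order kinetics (the one-compartment model):

$$\delta(t) = \Phi_1 + (\Phi_2 - \Phi_1)\,e^{-e^{\Phi_3} t}$$

where $\Phi_1$ is the asymptotic δ value (new diet plus discrimination),
$\Phi_2$ the initial value, and $e^{\Phi_3}$ the fractional incorporation
rate (1/day). The isotopic **half-life** is $\ln 2 / e^{\Phi_3}$ days.
Individual heterogeneity enters as Gaussian random effects on $\Phi_3$
(optionally $\Phi_1$, $\Phi_2$), and sex/age fixed effects shift $\Phi_3$ so
demographic groups get their own half-lives. A two-pool mixture
($p\,e^{-k_1 t} + (1-p)\,e^{-k_2 t}$) is available for comparison; on
single-pool data it is overparametrized and the fit reports that honestly.

**Discrimination** is $\Delta = \delta_\text{tissue} - \delta_\text{diet}$
per isotope, with optional C:N-based lipid normalization of δ¹³C, and is
analysed with a linear mixed model (diet, tissue, sex, age fixed;
individual random intercept; AIC ladder with a ΔAIC < 2 "simplest wins"
rule, final estimates by REML).

The curve can also be inverted as an **isotopic clock**:
`time_since_diet_shift()` maps an observed δ value back to days since the
diet change.

## Worked example

Simulate the emulated plasma δ¹³C experiment (half-life 9 days, individual
log-rate SD 0.25, measurement error 0.2‰) and refit it:

```r
library(isoturn)

truth <- trajectory_truth("plasma", "d13C", phi1 = -18.5, phi2 = -24.5,
                          half_life = 9)
dat <- simulate_trajectories(population_spec(20, 20), truth, seed = 1)
fit <- fit_turnover(dat)   # nonlinear mixed model, random effect on phi3
fit$half_life
#> # A tibble: 1 × 6
#>   group estimate lower upper log_rate log_rate_se
#>   <chr>    <dbl> <dbl> <dbl>    <dbl>       <dbl>
#> 1 all       9.48  8.48  10.6    -2.62      0.0571
```

The fitted population half-life is 9.48 days with a 95% Wald interval of
(8.48, 10.6) — the generating value of 9 days is comfortably inside.
`tidy(fit)` returns the parameter table, `glance(fit)` the AIC / likelihood
summary, and `autoplot(fit)` draws the individual trajectories with the
population curve.

Candidate models (sex/age effects on the rate) are compared with
`select_model()`, which implements the ΔAIC < 2 parsimony rule; control
animals are screened with `check_equilibrium()`; sampling designs are
stress-tested with `design_scenario()` + `run_design_sim()` (bias, SD and
percentiles of asymptote, intercept and half-life per candidate schedule)
and `compare_sample_sizes()` (empirical SE of the half-life versus the
number of animals).

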