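# cuspra

Empirical ecological-resilience assessment from ordinary monitoring time
series, built on the stochastic cusp catastrophe model.

Systems such as exploited fish stocks or forced marine communities can
cross tipping points: past a fold in their response surface they flip
between alternative stable states, with hysteresis. This package is for
ecologists who have a state-variable time series (a biomass, or a PC1
score summarising a community matrix) and two candidate drivers (e.g.
fishing pressure and temperature) and want to know (i) whether the
system's history is consistent with cusp-type discontinuous dynamics and
(ii) how close each observation sat to the tipping region.

## The model and the indicator

The state $z$ follows the cusp stochastic differential equation

$$dz_t = (-z_t^3 + \beta_t z_t + \alpha_t)\,dt + \sigma_z\,dW_t,$$

with the asymmetry factor $\alpha_t = \alpha_0 + \alpha_1 a_t$ (driver
$a$, e.g. fishing) shifting the system between low and high states, the
bifurcation factor $\beta_t = \beta_0 + \beta_1 b_t$ (driver $b$, e.g.
temperature) folding the response, and $z_t = w_0 + w_1 y_t$ the canonical
transform of the observed state. `fit_cusp()` maximises the
stationary-density likelihood
$f(z\mid\alpha,\beta) \propto \exp(\alpha z + \beta z^2/2 - z^4/4)$ over
the six coefficients. Multiple equilibria exist where Cardan's
discriminant $\delta = 27\alpha^2 - 4\beta^3 \le 0$ (the cusp area).

A four-criterion adequacy gate (`gate()`) guards interpretation:
pseudo-R² > 0.3, AICc at least 2 units below the linear alternative,
more than 10% of observations inside the cusp area, and a significant
state coefficient. If the gate passes, each observation is scored by its
control-plane geometry: horizontal distance to the bifurcation set
$H = |\alpha| - 2(\beta/3)^{3/2}$ (for $\beta>0$), vertical distance to
linearity $V = -\beta$, combined as $Ri = (2H + V)/3$ and squashed to

$$RA = \frac{\tanh(Ri)+1}{2} \in (0,1),$$

with 0 = low resilience (at the fold, close to a tipping point) and
1 = high resilience (linear response). The package also ships the full
simulation validation: cusp-SDE ensembles and chaotic / periodic / random
null series (`build_ensemble()`), the gate classification experiment
(`confusion_experiment()`), and the indicator hypothesis checks
(`hypothesis_experiment()`).

## Worked example

```r
library(cuspra)

dat <- sim_cusp_dataset(beta_mean = 2, seed = 42)  # 50-step series, two drivers
fit <- fit_cusp(dat, seed = 1)
glance(fit)
#>   logLik  AICc pseudo_r2 frac_in_cusp w1_pvalue converged  nobs n_params
#> 1  -36.2  86.3     0.923          0.2  1.67e-74 TRUE         50        6

gate(fit, fit_linear(dat))[, c("pseudo_r2","delta_aicc","frac_in_cusp","w1_pvalue","overall")]
#>   pseudo_r2 delta_aicc frac_in_cusp w1_pvalue overall
#> 1     0.923       40.6          0.2  1.67e-74 TRUE

res <- cuspra(fit)
glance(res)
#>   min_RA median_RA max_RA n_inside_cusp frac_inside_cusp  nobs
#> 1 0.0439     0.698  0.998            10              0.2    50
```

The fit is adequate (all four criteria pass: high pseudo-R², the cusp
beats the linear model by 40.6 AICc units, 20% of observations lie inside
the cusp area, and the state coefficient is significant). The resilience
series then says the system ranged from `RA` near 0.04 — sitting in the
multiple-equilibria region, primed to tip — up to 0.998 in phases with a
safely linear response; 10 of 50 time steps were spent inside the cusp
area. `autoplot(res)` draws the control-plane map and
`plot_resilience_timeline(res)` the RA trajectory. For file-based runs,
`run_pipeline(cuspra_config("input.csv", out_dir = "out"))` executes the
whole protocol (optional PCA reduction, fit, gate, resilience) and writes
CSV/JSON artifacts; it deliberately refuses to emit a resilience series
when the gate fails.

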