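# sizempm

Bayesian size-structured matrix population models (MPMs) for estimating
phytoplankton division rates and per-cell carbon fluxes from diel cell-size
distribution time series.

## The problem

For picophytoplankton such as *Prochlorococcus*, division rates cannot be
inferred from changes in cell abundance in the field: grazing, viral lysis
and physical transport remove cells at unknown rates. What those processes
plausibly leave untouched is the *relative* cell-size distribution. Over a
day–night cycle, photosynthetic carbon fixation pushes cells up through size
classes, respiration/exudation pulls them down, and division replaces one
large cell with two half-sized daughters. `sizempm` fits a discrete
size-structured matrix population model to counts over logarithmic size
classes (from flow cytometry) plus incident light, and reports the daily and
hourly division rate, daily and hourly carbon fixation and loss
(fg C cell⁻¹), and the photosynthetic parameters E_k and P_max — with full
posterior uncertainty.

## The model in brief

Size classes have boundaries v_i = v_1 2^((i−1)Δv); division shifts a cell
down exactly 1/Δv classes. In each time step dt a cell divides with
probability δ_i(t), shrinks one class with probability ρ_i, grows one class
with probability γ_i(t) ∝ γ_max s_γ(i) (1 − e^(−E(t)/E_k)), or stays. These
fractions fill a projection matrix whose column sums are 1 + δ_i(t); the
product of step normalizers is the relative cell number, giving the daily
division rate estimator

    μ̂ = (24/T) · log( 1ᵀ [ ∏_k B_k ] ω₀ ).

Observed counts are Dirichlet-multinomial around the projected mean
distribution (concentration σ controls overdispersion). A three-letter
grammar names model variants — fixation (b/p/f) × division (m/t) × loss
(x/b/f), e.g. `bmb`, `ftf` — all 18 supported. Inference is by an in-package
No-U-Turn HMC sampler with hand-coded adjoint (reverse-mode) gradients in
C++; 6 chains × 2000 iterations by default, split-R̂ ≥ 1.05 flags a fit
divergent. See the methods vignette
(`vignettes/size-structured-mpm.Rmd`) for the full model, priors, and design
choices.

## Worked example

Generate a synthetic diel experiment at the reference design (27 size
classes from 16 fg C, dt = 1/3 h, 46 h observed every 2 h, N = 10⁵ cells per
time point, σ = 200), fit the monotone-division model with carbon loss, and
read off the rates:

```r
library(sizempm)

grid <- size_grid(16, 1/8, 27)
scenario <- mpm_scenario("bmb", grid = grid, N_per_time = 1e5,
                         sigma = 200, seed = 101)
dat <- generate_dataset(scenario)
round(dat$rates, 3)
#>       mu_daily daily_fixation     daily_loss          p_max            e_k
#>          0.602         63.137         18.276        150.477        300.000

fit <- fit_mpm(dat$obs, dat$light, "bmb", grid = grid,
               chains = 2, iterations = 600, warmup = 300, seed = 202)
print(fit)
#> Size-structured MPM fit, model m_bmb (27 classes, dt = 0.3333333 h)
#>   2 chains x 600 iterations (300 warmup); max split-Rhat 1.011; 0 divergent transitions
#>   daily division   0.684 d^-1      (IQR 0.662-0.708)
#>   daily C fixation 63.68 fg C/cell (IQR 62.07-65.65)
#>   daily C loss     14.04 fg C/cell (IQR 12.68-15.48)
```

The fitted daily division rate (0.68 d⁻¹, posterior median) and carbon
fixation (63.7 fg C cell⁻¹ d⁻¹) recover the generating values (0.60, 63.1);
daily carbon loss, the least identified of the three fluxes at this
overdispersion level (effective information per time point is of order σ,
not N), comes back at 14.0 against a generating 18.3. `summary(fit)` gives
per-parameter posteriors with split-R̂; `predict(fit)` returns the fitted
mean size distributions; `plot(fit)` shows the fitted distributions and the
hourly division band; `simulate(fit)` draws posterior-predictive count
datasets.

Sensitivity machinery mirrors the observation-design experiments:
`extend_periodic()` + `window_plan()` + `sliding_window_fit()` refit inside
sliding 48-h windows, and `holdout_plan()` + `holdout_fit()` report train
and test size-distribution error under equally spaced thinning.
`fit_map()` provides the (restart-logged, deliberately instability-exposing)
maximum a posteriori / maximum likelihood benchmark.

A thin command-line wrapper for shell use lives at
`inst/cli/fit-mpm.R` (counts CSV + PAR CSV → draws CSV + JSON summary).

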