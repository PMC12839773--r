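# flatrode

Differential-flatness control synthesis under smooth random fluctuations.

## The problem

Biological and physiological control loops — eye movements tracking a
target, insulin regulating blood glucose — can be described by stochastic
generative models

```
dx/dt = f(x, θ) + G(x, θ) u + ζ_x ,      y = h(x, θ) + ζ_y ,
```

where `u` is the action and the fluctuations `ζ` are *smooth* random
signals rather than white noise. A system of this kind is **differentially
flat** when there is an output `ω = (ω₁, …, ω_m)` (the *flat output*)
through which every state and every action can be written in closed form:

```
x = A(ω, ω̇, …, ζ, ζ̇, …) ,      u = B(ω, ω̇, …, ζ, ζ̇, …) .
```

No differential equation needs to be integrated: choosing the goal
trajectory `ω_r(t)` immediately yields the open-loop action, and a
tracking law with poles placed at `−p`,

```
u = A(x,ζ)⁻¹ (v − b(x,ζ)) ,     v_i = ω_{r,i}^{(κ_i)} − Σ_j λ_{ij} (ω_i^{(j)} − ω_{r,i}^{(j)}) ,
```

drives the action discrepancy `ε_act = ω − ω_r` to zero along every sample
path — which is exactly the minimisation of the risk term of an expected
free energy in the active-inference reading of control.

`flatrode` provides, for control-affine models given symbolically:

* **Fluctuation model** — periodic smooth random functions: `L`-periodic,
  band-limited Gaussian trigonometric sums with `r = ⌊L/λ_w⌋` harmonics,
  exact derivatives/antiderivatives of every order, a "big" normalisation
  whose integrals converge to Brownian paths, and a Mill's-ratio + Rice
  tube-exceedance bound (`sample_srf()`, `srf_eval()`, `srf_integral()`,
  `tube_exceedance_bound()`).
* **Flatness engine** — the dynamical extension algorithm (Brunovský index
  gathering, flatness verdict, decoupling matrix), functional
  parametrisation with residual verification, linearising feedback,
  chain-form realisation and polynomial point-to-point steering
  (`brunovsky_analysis()`, `functional_parametrisation()`,
  `verify_parametrisation()`, `linearising_feedback()`,
  `brunovsky_realisation()`, `plan_point_to_point()`).
* **Tracking** — pole-placement gains, tracking controllers with
  oracle/mean fluctuation knowledge, bit-reproducible fixed-step RK4
  pathwise simulation, and active-inference discrepancy/risk metrics
  (`tracking_controller()`, `simulate_closed_loop()`,
  `discrepancy_metrics()`).
* **Worked systems** — the oculomotor model (eye on a screen under
  Listing's law; sigmoid / quatrefoil / hypocycloid gaze references), the
  input-delayed simple example with δ-flat parametrisation and two
  predictors (delayed observer, integral Picard predictor), and the
  Bergman glucose–insulin model demonstrating where generalised
  coordinates (linearised differentiation `d1()`) stop being adequate
  (`run_tracking_experiment()`, `simulate_delayed_tracking()`,
  `bergman_demo()`).

## Worked example

Certify the oculomotor model and run a closed-loop pursuit of a quatrefoil
curve under four smooth random fluctuation channels
(`L = 8, λ_w = 2, α = 10⁻⁵`, hence `r = 4` harmonics per channel), with the
oracle tracking law:

```r
library(flatrode)

model <- build_oculomotor()           # states (X, Y, vψ, vφ), torques (uψ, uφ)
cert  <- oculomotor_certificate(model)
cert
#> <flatness certificate>
#>   model: oculomotor (screen coordinates) (n = 4, m = 2)
#>   X = xX   kappa = 2
#>   Y = xY   kappa = 2
#>   verdict: FLAT (indices sum to the state dimension and the decoupling
#>   matrix is generically nonsingular)

ex <- run_tracking_experiment(reference = "quatrefoil", seed = 1,
                              mode = "oracle", dt = 1e-3)
ex
#> <oculomotor tracking experiment>
#>   reference: quatrefoil | mode: oracle | alpha = 1e-05 | seed = 1
#>   max |eps_act| = 9.61e-13, RMS = 8.66e-13, risk = 2.35e-24

glance(ex$metrics)
#> # A tibble: 1 × 5
#>       risk  ise_act ise_obs max_eact rms_eact
#>      <dbl>    <dbl>   <dbl>    <dbl>    <dbl>
#> 1 2.35e-24 4.71e-24       0 9.61e-13 8.66e-13
```

The Brunovský indices `κ = (2, 2)` sum to the state dimension, certifying
`(X, Y)` as a flat output. With full knowledge of the fluctuation paths the
tracking law compensates them exactly: the maximal action discrepancy over
a full period of the curve (`9.6 × 10⁻¹³` m) and the risk proxy
(`2.4 × 10⁻²⁴`) sit at the integration floor — the reference and actual
curves are indistinguishable. `plot_tracking_plane(ex$trace)` draws the
reference (red) and tracked (blue) curves; `autoplot(ex$trace)` shows the
per-component time courses.

A thin command-line interface over the same functions is installed at
`inst/cli/flatrode` (subcommands `srf`, `oculo`, `track`, `delay`,
`gencoords`).

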