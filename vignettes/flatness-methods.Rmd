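---
title: "Flatness-based control synthesis under smooth random fluctuations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flatness-based control synthesis under smooth random fluctuations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flatrode)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices behind the symbolic
engine, and the limits of what the test suite demonstrates.

## The model class and its assumptions

`flatrode` works on control-affine stochastic generative models

$$\dot x = f(x,\theta) + G(x,\theta)\,u + N(\zeta\text{-jet}), \qquad
  y = h(x,\zeta,\theta),$$

with smooth, pathwise-interpretable fluctuations $\zeta$. Because every
fluctuation is a trigonometric polynomial (see below), each sample path of
the closed loop is an ordinary differential equation — a random ODE — and
all statements (parametrisation, tracking, risk) are *pathwise*: they hold
for every realisation, not only in expectation.

A model is differentially flat with flat output $\omega$ when all states
and inputs are closed-form functions of $\omega$ and finitely many of its
derivatives (plus the fluctuation jet). The package certifies candidates
constructively with the dynamical extension algorithm: differentiate each
component along the model flow until an independent input direction
appears ($\kappa_i$ differentiations), declare the tuple flat iff
$\sum \kappa_i = n$ and the decoupling matrix $A$ — the matrix of input
coefficients in $\omega_i^{(\kappa_i)}$ — is generically nonsingular.
Certificates verify these *constructive* conditions only: the
non-existence of differential relations among the components (differential
independence in the abstract definition) is not algorithmically checkable
here, and the certificate's print method says so.

**Scope.** The engine covers static-feedback-linearisable, control-affine
systems — the class containing every worked system in the package
(simple generic example, double integrator, oculomotor, Bergman, car).
When an input direction appears early but is dependent on previously
gathered directions, genuine dynamic extension (integrator augmentation on
inputs) would be required; such candidates are rejected with a diagnostic
rather than silently mis-certified. Phase I is order-dependent across
components: candidates are processed in the order given, and accumulated
input directions are tracked by row-rank growth of the input-coefficient
matrix at random generic points.

## The fluctuation model

`sample_srf(L, lambda_w, mode, alpha, seed)` draws

$$\zeta(t) = \alpha\Big(a_0 + \sum_{j=1}^{r} a_j \cos\tfrac{2\pi j t}{L}
 + b_j \sin\tfrac{2\pi j t}{L}\Big), \qquad r = \lfloor L/\lambda_w\rfloor.$$

| parameter | units | default | role |
|---|---|---|---|
| `L` | time | 8 (study configuration) | period of the sum |
| `lambda_w` | time | 2 (study), 0.01 (Brownian regime) | wavelength; band limit $2\pi/\lambda_w$ |
| `mode` | — | `"standard"` | coefficient normalisation |
| `alpha` | signal units | 1 (oculomotor runs use $10^{-5}$) | multiplicative amplitude |
| `seed` | — | — | one integer per function; fixed draw order $a_0, a_1, b_1, \ldots$; the caller's RNG state is restored |

In **standard** mode every coefficient is i.i.d. $N(0, 1/(2r+1))$, so the
pointwise variance is $\alpha^2 (r+1)/(2r+1)$ — the law used by all
oculomotor experiments. In **big** mode the DC coefficient has variance
$2/((2r+1)\lambda_w) \approx 1/L$ and each harmonic coefficient twice
that. The factor 2 is the two-sided spectral weight: the DC term occupies
one frequency, every $j>0$ cosine/sine pair covers $\pm 2\pi j/L$. With
this flat unit spectral density the exact identity

$$\mathrm{Var}\Big[\int_0^t \zeta\Big]
  = \sigma_0^2 t^2 + \sigma_h^2 \frac{Lt - t^2}{2} \approx t$$

holds for all $t$ up to the period, which is the Brownian-limit property
the big normalisation exists for (verified by Monte Carlo at
$\lambda_w = 0.01$ in the test suite). An equal-variance big mode would
instead give $\mathrm{Var}[\int_0^1\zeta] \approx (L+1)/2L \approx 0.56$;
the split is therefore forced by the Brownian limit, not a free choice.

Derivatives and antiderivatives are computed term-wise in closed form
(one differentiation maps $(a_j, b_j) \mapsto (\omega_j b_j, -\omega_j
a_j)$), so fluctuation jets of any order are exact — no finite
differencing anywhere.

The tube-exceedance bound

$$P\Big(\sup_{[0,T]}\zeta \ge u\Big) \le
 e^{-u^2/2\sigma^2}\Big(\frac{\sigma}{\sqrt{2\pi}\,u}
 + \frac{T\lambda_2}{2\pi\sigma}\Big),
 \quad \sigma^2 = E[\zeta^2],\ \lambda_2^2 = E[\dot\zeta^2],$$

is assembled as a Mill's-ratio tail term plus a Rice up-crossing term
sharing the Gaussian factor. The bound is validated *as an upper bound*
against Monte Carlo sup-statistics (it is vacuous near $u \approx \sigma$,
where it exceeds 1 and is clipped for reporting).

**What the generator emulates, and what it does not.** The sampler
reproduces band-limited, stationary, Gaussian, periodic fluctuations with
a chosen correlation length — the regime in which smooth-fluctuation
models of biological noise are formulated. It does not emulate
non-stationarity, heavy tails, state-dependent noise, or measurement
quantisation. Consequently, passing tests demonstrate correctness of the
calculus and of the closed-loop laws *under the stated noise model*; they
do not certify robustness to structurally different disturbances (that is
the province of robust/model-free control, deliberately out of scope).

## The symbolic engine and its numerics

There is no computer-algebra dependency: expressions are base-R language
objects. Partial derivatives come from `stats::D`, substitution from
`substitute()`, and a constant-folding pass keeps expressions compact.
Two numerical conventions do the work a CAS simplifier would:

* **Zero testing.** An expression is "identically zero" if constant
  folding reduces it to 0, or if it evaluates to zero — to 12 significant
  digits relative to a term-magnitude scale — at random generic points
  (drawn once, fixed seed, magnitudes in $[0.15, 1.35]$ to stay clear of
  poles and of the origin's accidental zeros). The magnitude scale is the
  same expression with all subtractions replaced by additions, so the
  tolerance tracks the size of the cancellations being tested.
* **Genericity.** Rank growth in Phase I and nonsingularity of the
  decoupling matrix are decided at the same random points; singular loci
  are additionally guarded at run time — every controller refuses to
  invert a decoupling matrix whose determinant falls below $10^{-12}$ and
  reports the state where it happened. (On the oculomotor model the
  diagonal entries are bounded below by $d^2/(2dI_e) > 0$, so no
  trajectory can reach a singularity; the experiment asserts this along
  every simulated path.)

The functional parametrisation inverts the stacked derivative-chain map by
triangular elimination: at each pass it solves any chain equation that is
affine in its single remaining unknown state (affinity checked by the
zero test on the second partial), substitutes, and repeats; inputs are
then recovered through a symbolic adjugate solve ($m \le 3$). A failure to
triangularise is reported with the unsolved equations rather than forced
numerically. Residual verification substitutes the parametrisation into
every model equation and zero-tests the difference — the informative
output is the residual expression itself.

## Simulation and tracking

Closed loops are integrated by fixed-step classical RK4, one sample path
at a time. The default step `dt = 1e-3` time units resolves all spectral
content of the study fluctuations (wavelengths $\ge 0.1$); an
order-verification test confirms the terminal error scales as
$O(\mathrm{d}t^4)$. Fixed step plus seeded fluctuations make every trace
bit-reproducible. The action is evaluated at every RK4 stage (continuous
feedback); traces record states, actions, outputs, mean-predicted outputs
and both discrepancies at the nodes, as a tibble with metadata in
attributes.

Tracking gains default to a $\kappa$-fold pole at $p = 2$ per time unit
(any Hurwitz gain vector is accepted and validated via `polyroot`); gains
are recorded in the trace metadata. Controllers come in two knowledge
modes: **oracle** substitutes the true fluctuation jets (the
full-knowledge assumption under which the pathwise laws cancel the noise
exactly), **mean** sets them to zero (the law computable from the mean
model). Measurement of the flat-output jets uses the certificate's
derivative chains evaluated at the current state — full state knowledge is
assumed throughout; observers for hidden states are out of scope.

Two measurement conventions deserve note:

* **Decay-rate fits** use a log-linear regression of the error norm over
  the central $[0.2, 0.8]$ window, truncated at a numerical floor. With a
  repeated pole the generic transient is $(c_1 + c_2 t)e^{-pt}$, whose
  log-slope is biased by up to $\sim 20\%$ on any finite window; rate
  recovery is therefore measured from the eigenmode initial condition
  $\dot e(0) = -p\,e(0)$, where the norm is exactly exponential. This is a
  property of repeated poles, not of the implementation.
* **Linear-response scaling** of the mean-mode error in the noise
  amplitude $\alpha$ is exercised on the simple generic example, where the
  fluctuation-to-action coupling is $O(1)$. On the oculomotor model the
  torque-channel fluctuations are amplified by $1/(2I_e) \approx 1.2
  \times 10^6$, so $\alpha \ge 10^{-6}$ already leaves the linear regime
  (and the quadratic position kinematics give finite-time escape under
  zero action — which is why the risk-ordering comparison against the
  zero-action baseline uses a short horizon).

The risk proxy is $\int \tfrac12 \varepsilon_{act}^\top \Pi\,
\varepsilon_{act}\,dt$ (trapezoid rule, $\Pi$ symmetric positive definite,
identity by default): the pointwise Kullback–Leibler divergence between
Gaussian anticipated and goal-conditioned outcome densities with equal
covariances, integrated along the path. The correspondence with the risk
term of an expected free energy is asserted as an *ordering* property
(tracking < open loop < zero action on paired offset experiments), not as
an equality.

## Delay handling

For the input-delayed simple example the flat parametrisation survives
with a time shift: states keep their undelayed expressions, the action is
the undelayed law evaluated at $t + \tau$. Since the shift operator
commutes with differentiation and all static maps, verification reduces
to the undelayed residuals — which is how `verify_delta_flat()` checks it.

Predictive tracking closes the loop with the undelayed law applied to a
prediction of $x(t+\tau)$:

* the **delayed observer** $\dot{\hat x} = f(\hat x, u(t)) + K_{obs}(x(t)
  - \hat x(t-\tau))$, with $K_{obs}$ a free parameter whose convergence is
  verified empirically per run (no certificate is computed);
* the **integral predictor**, the Picard fixed point of $z(s) = x(t) +
  \int_t^s f(z, u(\xi - \tau))\,d\xi$ over the prediction window, with
  trapezoidal quadrature (observed order ≥ 2), tolerance $10^{-10}$, an
  iteration cap of 100 and warm starts from the previous step;
  non-convergence is an error carrying the last residual, never a silent
  truncation.

Histories (committed actions, observer states) are uniform ring buffers at
the simulation step with linear interpolation, so the delayed loop needs
$\tau \ge \mathrm{d}t$. Both predictors are exact in the zero-delay limit.

## Generalised coordinates

The linearised differentiation `d1()` acts on polynomials in jet symbols
and deletes, after each product-rule application, every monomial carrying
**two or more differentiated factors** (counting multiplicity). This is
the operative content of first-order truncation: all cross products of
derivatives vanish, a single differentiated factor of any order survives
with arbitrary undifferentiated cofactors, `d1` is linear and coincides
with full differentiation on expressions linear in the variables, and
repeated application yields the local linear approximation
$\mathrm d^k F(\xi)/\mathrm dt^k = \nabla F(\xi)\,\xi^{(k)}$. (Published
renderings of the truncation rule are ambiguous about which factor orders
count; this reading is the unique one consistent with all the worked
computations the package reproduces, in particular keeping $G X''$ while
dropping $X'G'$ in the glucose chain.)

The consequence for control: chains of Brunovský index $\le 2$ are
untouched by the truncation (the first differentiation substitutes the
dynamics before any derivative symbols exist), so the car ($\kappa = 1$)
and oculomotor ($\kappa = 2,2$) tracking laws are identical under either
operator. At index 3 — the Bergman glucose chain — the full third
derivative carries $-2\dot X\dot G$, which `d1` deletes; a law built on
the truncated chain leaves the closed-loop error steered by that term.
`bergman_demo()` runs the paired comparison.

**Bergman defaults** (not fixed by any published table; synthetic,
literature-plausible magnitudes, all overridable): rates $k_1 = 0.03,
k_2 = 0.02, k_3 = 0.01, k_4 = 0.05\ \mathrm{min}^{-1}$, basal levels
$G_b = 110$ mg/dL, $I_b = 10$ mU/L, meal bolus $B = 5$ mg/dL/min with
onset stiffness $0.8\ \mathrm{min}^{-1}$ at $t_{bol} = 30$ min and washout
$0.06\ \mathrm{min}^{-1}$. The default comparison tracks a sigmoid glucose
descent (140 → 100 mg/dL) across the meal window so that
$\dot X \dot G \ne 0$ along the run; with a constant reference and no meal
the driving term vanishes and both laws coincide, which the suite also
checks. Problem sizes: the demo integrates 120 min at
$\mathrm{d}t = 0.02$ min (0.05 in the tests); oculomotor experiments run
one curve period at $\mathrm{d}t = 10^{-3}$–$2\times10^{-3}$ s; the
Monte Carlo checks use 20 000 seeds (pointwise variance), 2 000
(Brownian limit) and 5 000 (tube bound).

## Package shape

The core objects (models, certificates, parametrisations) are symbolic S3
lists — inherently non-tabular — while everything time-indexed or summary
(traces, metrics, tidy/glance views) is returned as tibbles with
`autoplot()` methods, so analysis pipelines compose in the usual
data-frame idiom. Model definitions, certificates and parametrisations
serialise to JSON with a documented infix expression grammar; a thin
command-line script (`inst/cli/flatrode`) exposes the samplers and the
worked experiments to shell users.

## Known limitations

* Only static-feedback-linearisable control-affine systems; no dynamic
  extension, no necessary-and-sufficient flatness conditions, no
  differential-independence verification.
* Full state is assumed measurable; no observers or algebraic estimators
  for hidden states.
* Gaussian, stationary, band-limited periodic fluctuations only; no Itô
  calculus, no wavelet series, no state-dependent noise.
* The expected-free-energy connection is implemented as discrepancy and
  risk-proxy metrics plus ordering properties — not as a variational
  optimisation scheme.
* The symbolic layer trusts generic-point zero testing; pathological
  expressions that vanish on all test points but not identically would be
  mis-classified (ten independent points make this astronomically
  unlikely for the algebraic expressions arising here).
* Delay support covers input delays on flat systems with full state
  knowledge; hidden-state delays (general π-flatness) are not implemented.
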