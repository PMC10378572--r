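---
title: "Estimating vocal-fold oscillator models from voice signals: models, algorithms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating vocal-fold oscillator models from voice signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Phonation is modelled here with an asymmetric one-mass body-cover
oscillator: each vocal fold is a lumped mass whose mucosal cover carries a
small-amplitude surface wave, and the two folds are coupled through the
glottal pressure. In dimensionless form the fold displacements
$\xi_r(t)$, $\xi_l(t)$ obey a pair of coupled Van der Pol equations

$$\ddot\xi_r + \beta(1+\xi_r^2)\dot\xi_r + \xi_r - \tfrac{\Delta}{2}\xi_r
  = \alpha(\dot\xi_r + \dot\xi_l), \qquad
  \ddot\xi_l + \beta(1+\xi_l^2)\dot\xi_l + \xi_l + \tfrac{\Delta}{2}\xi_l
  = \alpha(\dot\xi_r + \dot\xi_l),$$

with three parameters: the glottal-pressure coupling $\alpha$, the lumped
mass/spring/damping coefficient $\beta$, and the asymmetry $\Delta$ that
detunes the restoring forces of the two folds. The damping term
$\beta(1+\xi^2)\dot\xi$ is dissipative everywhere; the only energy input is
the coupling term, so the symmetric system self-oscillates exactly when
$2\alpha > \beta$. The clinical reference values for a normal adult male
voice are $\alpha = 0.5$, $\beta = 0.32$, $\Delta = 0$. Asymmetry
($\Delta > 0$) is the model's handle on pathological phonation: unilateral
stiffness changes detune one fold against the other.

Displacement converts to glottal volume velocity through the static
geometry $u_0(t) = \tilde c\, d\, (2\xi_0 + \xi_l + \xi_r)$ with
$\xi_0 = 0.1$ cm (half glottal width at rest), $d = 1.75$ cm (fold
length) and $\tilde c = 5000$ cm/s (mid-fold air particle velocity). The
model excludes fold collision (no glottal closure), so $u_0$ never
clips; displacements of the dimensionless model are used directly as cm,
matching the mixed convention of the defining constants.

Two estimation modes are provided:

* **Backward (ADLES, `fit_adles`)**: the parameters are fitted to a
  *reference glottal flow* — from inverse filtering of a recording, or
  from a synthetic generator — by minimizing
  $F = \int_0^T (u_0 - u_g)^2\,dt$.
* **Forward-backward (ADLES-VFT, `fit_adles_vft`)**: no glottal reference
  is assumed. The model flow is propagated through a one-dimensional
  vocal-tract wave model
  $u_{tt} = c^2 u_{xx} + f(x,t)$ on a tube of length $L$ (glottis at
  $x=0$, lips at $x=L$), and the parameters *and* the distributed source
  profile $f(x,t)$ are fitted to the recorded lip signal. With $f \equiv 0$
  the tract is the uniform-tube (Webster horn) limit; $f$ absorbs
  yielding-wall, coupling and radiation effects.

## Adjoint gradients

Both fitters are plain gradient descent; the gradients come from an
adjoint (costate) system integrated backward from zero terminal
conditions. For the backward mode, stationarity of the constrained
Lagrangian with respect to the fold displacements gives

$$\ddot\lambda - \beta(1+\xi_r^2)\dot\lambda + \alpha(\dot\lambda+\dot\eta)
  + (1-\tfrac{\Delta}{2})\lambda + 2\tilde c d\, R = 0,$$

with the mirrored equation for $\eta$ (left fold) and
$\lambda(T)=\dot\lambda(T)=\eta(T)=\dot\eta(T)=0$. An equivalent
"algebraic-companion" form of this system is often quoted, in which the
first-derivative terms are replaced using the relations
$\beta(1+\xi_r^2)\lambda = \alpha(\lambda+\eta)$ and its mirror; those
relations are generally incompatible with the zero terminal conditions, so
the two forms differ as initial-value problems. This package integrates
the variational form by default — it is the form whose gradients agree
with finite differences of the loss, which is the adjudicating test of the
module (relative error $\sim 10^{-5}$, asserted at $10^{-3}$) — and
reports the pointwise residuals of the algebraic relations as diagnostics
(`adjoint_form = "algebraic"` selects the literal companion form).

The parameter gradients are then the quadratures

$$F_\alpha = \int -(\dot\xi_r+\dot\xi_l)(\lambda+\eta)\,dt,\quad
  F_\beta = \int (1+\xi_r^2)\dot\xi_r\lambda + (1+\xi_l^2)\dot\xi_l\eta\,dt,\quad
  F_\Delta = \tfrac12\int \xi_l\eta - \xi_r\lambda\,dt.$$

In the forward-backward mode the residual is observed at the lips; it is
mapped to the glottis by the **exact discrete transpose** of the wave
propagation operator. Because the leapfrog scheme starts from rest with
time-invariant coefficients, the map from glottal Dirichlet data to the
lip trace is a causal discrete convolution, and its transpose is obtained
by time-reversing input and output of the same solver. This realizes the
sensitivity factor $\partial u_L/\partial u_0$ without forming a Jacobian
and satisfies the inner-product adjoint identity to machine precision
($\sim 10^{-14}$, asserted at $10^{-6}$). End-to-end (ODE + PDE) gradients
then match finite differences to $\sim 10^{-6}$ relative.

Both losses support standardization (zero mean, unit variance) of the two
series being compared, with the chain rule taken through the mean and
standard deviation so that adjoint gradients remain exact for the
standardized loss.

## Normalization and identifiability

Standardization is *necessary* in the forward-backward mode — microphone
gain and transmission loss make the absolute scale of a recording
meaningless — but it discards amplitude information, with two
consequences that shaped the defaults:

* In the backward mode the reference flow and the model flow share
  physical units, and the limit-cycle amplitude carries most of the
  information about $\alpha$ and $\beta$. `fit_adles` therefore compares
  raw flows by default (`normalize = FALSE`); with standardization on,
  descent stalls in a shape-only valley.
* In the forward-backward mode the standardized lip loss leaves $\beta$
  weakly identifiable: free-$\beta$ descent lets $\beta$ wander and drags
  $\alpha$ and $\Delta$ with it. `fit_adles_vft` therefore holds $\beta$
  at its initialization by default (`fit_beta = TRUE` restores the full
  three-parameter descent). Reported parameter errors for this family of
  methods are customarily quoted for $\alpha$ and $\Delta$ only, which is
  consistent with this choice.

Two structural symmetries are handled explicitly. The model is invariant
under negating $\Delta$ while swapping the folds, so $\Delta$ is
identifiable from flow data only up to sign; fitted values are reported
with the $\Delta \ge 0$ convention. And the all-zero state is an exact
equilibrium, so simulations (and the generator) start from a small
symmetric perturbation $(0.01, 0, 0.01, 0)$ rather than the literal
at-rest state; with quiescent positions exactly zero and zero velocities
the model would simply stay at rest.

## The optimizer

Three step rules are provided. `adaptive_max` is the classic recipe —
a step of fixed length `step_scale` $/\max(|F_\alpha|,|F_\beta|,|F_\Delta|)$
along the gradient; it descends reliably but crawls near the optimum
because the step length never adapts to the local scale of each
parameter. `fixed` multiplies the raw gradient by `step_scale`. The
default `rprop` adapts a per-parameter step from the *sign* of the
gradient (grow 1.2x while the sign is stable, halve on a sign flip,
capped at 10x `step_scale`); it is still plain gradient descent — no
conjugate directions or curvature estimates — and recovers noiseless
synthetic truths to about 1% in a few hundred iterations where the
fixed-length rule needs many more. $\beta$ is floored at $10^{-3}$ to
avoid the undamped degenerate system. Iteration stops when the relative
loss change stays below `loss_tol` ($10^{-6}$) for three consecutive
iterations, and the best-loss iterate is returned.

The profile update in the forward-backward loop is a Landweber iteration:
the standardized lip residual-gradient is propagated backward by time
reversal (a Neumann flux drive at the lip, homogeneous Dirichlet at the
glottis, zero conditions at the final time) and added to $f$ with a step
length found by monotone backtracking (halve until the lip misfit
decreases, then grow 1.5x for the next iteration). The backtracking is
essential: the standardized loss is bounded even for absurd profiles, so
any fixed aggressive step can wander onto a flat garbage plateau without
it. The literal pointwise update $f \leftarrow f + \iota(z/c^2 + u)$ and
its variants remain available in `update_profile` — the printed form of
this rule is typographically ambiguous, and all parsings descend for
small steps — but the fitting loop uses the raw time-reversed field
direction, which is the steepest-descent direction for the lip misfit up
to a positive scale.

### What is (and is not) recoverable in $f(x,t)$

The full space-time field $f$ is heavily underdetermined by one scalar
lip trace, and a *time-constant* profile $f(x)$ is essentially invisible
to the standardized loss (its quasi-static lip contribution is absorbed
by the mean/variance normalization — verified numerically). What descent
from $f \equiv 0$ recovers is the component of $f$ in the range of the
time-reversal (adjoint) operator with time variation inside the signal
band. The recovery study in the test suite therefore uses a smooth,
band-limited, adjoint-range truth profile (the `"smooth"` preset of
`synth_speech_case`); on that identifiable component the recovered
profile correlates with truth above 0.95 in an inverse-crime setting
(same solver generates and fits). No claim is made about recovering
arbitrary profiles from real recordings.

## The wave solver

Second-order finite differences with leapfrog time stepping on a uniform
grid; Dirichlet glottal data, zero-gradient Neumann lip condition via a
ghost node (a first-order Sommerfeld absorbing option is available), zero
initial conditions, Courant number $c\,\Delta t/\Delta x \le 1$ enforced.
When `dt` is not supplied the solver picks the Courant-1 step, at which
the discrete scheme propagates plane waves exactly; run slightly below
the limit to measure genuine discretization error. The scheme starts from
the same rest state at the two fictitious initial levels, which makes the
input-to-trace maps exactly time-invariant — the property the exact
discrete transpose (and hence ADLES-VFT's gradient correctness) rests on.
Against the d'Alembert solution before the first reflection the solver is
within 0.1% RMS at 400 cells at Courant 0.95, and refinement shows clean
second-order convergence for smooth data (an abruptly switched-on sine
has a non-smooth wavefront that caps the observable order at the front —
the convergence test uses a windowed pulse for this reason).

Defaults ($L = 17.5$ cm, $c = 35000$ cm/s, $\rho = 0.00114$ g/cm$^3$,
$A_L = 2$ cm$^2$) are standard adult cgs values. The lip pressure-velocity
conversion is the linear map $u = A_L/(\rho c)\, p$ (gain $\approx 0.0501$
at the defaults).

## Time scales

The oscillator evolves in dimensionless model time with natural frequency
1 rad per unit; a fundamental frequency $f_0$ maps model time to seconds
via $t_{\mathrm{s}} = t_{\mathrm{model}}/(2\pi f_0)$. The default for
synthesis is $f_0 = 150$ Hz; estimation from audio uses autocorrelation
pitch detection (50-500 Hz search, parabolic peak refinement). Note that
the *realized* limit-cycle period differs by a few percent from the
linearized $2\pi$, so the cycle rate of a synthesized flow is close to,
but not exactly, the nominal $f_0$; comparisons against synthesized
signals should use the realized rate (the Poincare crossing times give it
directly).

## Dynamics characterization

Fitted models are interpreted through their phase-space behavior. The
Poincare section is the zero-velocity plane of one fold; crossings in the
positive-to-negative direction are displacement maxima, detected with
sub-sample accuracy by linear interpolation after discarding the leading
75% of the trajectory (defaults: 2000 model-time units total, so roughly
80 post-transient cycles). Crossing values are clustered by single
linkage at $10^{-2}$ times the steady amplitude; the cluster count is the
period of the steady orbit, and a count above 12 flags a torus
(quasi-periodic orbits fill a band of the section). Entrainment is the
ratio of right to left crossing counts over the same window, reduced by
the greatest common divisor. These defaults are a compromise: tight
enough to separate period-1 from period-2 orbits, loose enough not to
fragment a noisy cluster; single-linkage chaining can merge a *densely
sampled* torus band into few clusters, so torus detection at very long
durations should reduce the window or use the cap on the crossing-count
spread.

The regime map ties parameter regions to phase-space behavior and
pathology labels: period-1 with $\Delta < 0.5$, $\alpha > 0.25$ is
normal phonation; period-1 near $(\Delta, \alpha) = (0.6, 0.35)$
indicates neoplasm; period-2 near $(0.6, 0.3)$ phonotrauma; a torus near
$\Delta = 0.85$ vocal palsy ("near" means within $\pm 0.05$,
configurable). Two caveats from direct simulation of the model as
written, at $\beta = 0.32$ from the standard small perturbation: the
phonotrauma-region point $(\alpha, \Delta) = (0.3, 0.6)$ lies just below
the oscillation threshold and decays to rest (a fine scan shows decay for
$\alpha \le 0.30$ and a period-1 cycle for $\alpha \ge 0.302$, with no
period-2 window), and the palsy-region point shows a dense torus-like
crossing band over the default window that locks toward 1:1 over much
longer horizons. The classification rules therefore operate on the
*observed* summary (period counts, torus flag) rather than re-deriving it
from the parameter point, and the regime battery in the acceptance suite
reports what the model as specified actually produces.

Two scalar features summarize trajectories for downstream discrimination.
The largest Lyapunov exponent uses Benettin's tangent-space method with
the analytic Jacobian, renormalizing every 5 model-time units after a
100-unit transient; a stable cycle gives 0 (the neutral direction along
the flow), verified against the analytic $-1$ of $\dot x = -x$. The Hurst
exponent uses rescaled-range analysis over dyadic windows with the
Anis-Lloyd-Peters small-sample correction; the minimum window defaults to
32 because smaller windows are dominated by the correction itself (with
the default, seeded white noise gives $0.50 \pm 0.01$, fractional
Gaussian noise with $H = 0.7$ about $0.64$ — the well-known downward
bias of rescaled-range analysis for persistent series — and a pure trend
about $0.97$).

## The synthetic-case generator

`synth_glottal_case` and `synth_speech_case` generate fully specified
cases: known $(\alpha, \beta, \Delta)$, initial conditions, geometry,
optional tract profile, fundamental frequency (default 150 Hz), and
seeded Gaussian noise added at a stated fraction of the signal's standard
deviation (1% noise is a 40 dB SNR). Everything is reproduced bitwise
from the seed. The generator emulates sustained steady phonation as the
model itself produces it; it does **not** emulate jitter and shimmer,
fold collision, aspiration noise, room acoustics, or microphone
coloration, so passing recovery tests demonstrate correctness of the
estimation machinery under the model's own assumptions — not robustness
to the full variability of clinical recordings.

Problem sizes used in the shipped studies: backward-mode references are
50 model-time units at $dt = 0.02$ (about 8 cycles, 2500 samples);
forward-backward cases use a 50-cell tract at the Courant-1 step
($10^{-5}$ s) for 50 ms of signal, and the end-to-end gradient checks a
50-cell, 30 ms grid. These are deliberate desk-scale choices: every
quantity asserted in the tests is recomputed from scratch at these sizes,
and the sizes are stated here so they can be scaled up.

## Inverse filtering

`inverse_filter` implements two-pass iterative adaptive inverse filtering
as a utility (not a contribution): alternating low-order glottal and
order-$f_s/1000 + 2$ vocal-tract all-pole models estimated by Burg linear
prediction, with leaky integration (coefficient 0.99) cancelling the lip
radiation derivative, pre-emphasis 0.97. On a constructed vowel (known
pulse-train flow through a known all-pole filter) the recovered flow
correlates above 0.9 with the truth. The output is standardized, since
the absolute flow scale is not recoverable from audio.

## Known limitations

* The phase-space regime table is reproduced only where the printed model
  actually produces the printed behavior (see the caveats above); this
  package reports computed values rather than adjusting the model.
* The vocal tract is static and one-dimensional; no time-varying area
  function, no nasal branch, no fold collision.
* Gradient descent with the recommended initialization converges to the
  study truths in the shipped settings, but the loss surface of
  oscillator fitting is multimodal in general; distant initializations
  can lock onto harmonically related minima.
* WAV input is uncompressed PCM/float only.
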