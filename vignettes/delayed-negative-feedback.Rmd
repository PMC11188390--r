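---
title: "Delayed negative feedback oscillators: models, strong-feedback limits, and singular Hopf bifurcations"
author: "ddnf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed negative feedback oscillators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddnf)
```

## The models

Delayed negative feedback is one of the canonical motifs of physiological
regulation: a variable $x(t)$ (a circulating cell population, a protein
concentration, a muscle response) suppresses its own production, but only
after a lag $\tau$ imposed by maturation, transcription, or signal
transport.  The scalar prototype is

$$ x'(t) = f\big(x(t-\tau)\big) - b\,x(t), $$

with $f$ decreasing.  When the delay is long enough relative to the
recovery rate $b$, the loop "forgets" its own state and oscillates.  The
package implements the family of feedback laws most used in this setting:

* **Hill feedback** $f(x) = 1/(1+x^p)$ with decay $b > 0$: the
  Mackey-Glass equation of hematopoietic control.  The exponent $p$ sets
  the steepness of the repression.
* **Sigmoidal feedback** $x' = -\tanh(\kappa\,x(t-\tau))$ (no decay): a
  minimal saturating negative feedback with gain $\kappa$.
* **Wazewska-Lasota** $x' = a e^{-c\,x(t-\tau)} - b x$: the exponential
  red-blood-cell production model.
* **Threshold and sign feedback**: the strong-feedback limits
  ($p \to \infty$, $\kappa \to \infty$) in which production switches
  discontinuously at the level 1 (Hill) or 0 (sigmoidal).
* **Reduced equations** $u' = e^{-u(t-\tau)} - b_1$ (Wright type) and
  $u' = -e^{u(t-\tau)} - u - b_1$: the leading-order equations governing
  small oscillations near the two Hopf points of the steep Hill model
  (below).
* A **linear** kind $x' = -r\,x(t-\tau)$, used to validate the integrator
  against the exact neutral solution $\cos(\pi t/2\tau)$ at
  $r = \pi/(2\tau)$.

All parameters are validated once, at `model_spec()` construction.  The
Hill function is always evaluated through $\exp(p \log x)$ with the
exponent clamped at $\pm 745$, so exponents of several hundred remain
exact to double precision instead of overflowing (already $35^{20}
\approx 10^{31}$).

## Numerical integration: the method of steps

`dde_integrate()` advances the solution one delay interval at a time.  On
each interval the delayed state is a *known* function — it was computed on
the previous interval — so the DDE becomes an ODE, integrated with the
classical fixed-step fourth-order Runge-Kutta scheme.  Three choices
matter:

* **The step divides the delay exactly** ($h = \tau/\texttt{steps\_per\_delay}$).
  The derivative discontinuities that the method of steps propagates from
  $t = 0$ to $t = \tau, 2\tau, \dots$ then always sit on mesh nodes, where
  one-sided derivatives are stored, and the formal order of the scheme is
  preserved.
* **Dense output.**  Every node stores $(x, x')$, and evaluation anywhere
  uses cubic Hermite interpolation (`traj_eval()`).  The RK stages at
  midpoints read the delayed state from this interpolant; its $O(h^4)$
  accuracy matches the integrator's.
* **No adaptive stepping.**  Runs are bitwise reproducible, and the
  discontinuity bookkeeping stays trivial.  At the problem sizes used here
  (hundreds of delay intervals, 200 steps each) a run takes well under a
  second, so adaptivity would buy nothing.

The default `steps_per_delay = 200` leaves the measured oscillation period
invariant to $10^{-11}$ relative under step halving for the Mackey-Glass
runs shown below; the suite asserts $10^{-5}$.  Against an independent
adaptive solver (`deSolve::dede`, tolerances $10^{-10}$) trajectories agree
to about $10^{-9}$.

For the **threshold and sign kinds** the right-hand side is piecewise
linear, and integration is *exact*: between production switches the
solution is an explicit exponential (or linear) segment.  A switch happens
one delay after the solution itself crosses the threshold level; those
crossing times have closed forms inside a segment, are inserted as mesh
nodes, and are propagated forward by $\tau$.  `exact_threshold_integrate()`
exposes this event engine directly and reports the switch times, which are
exactly the extrema of the relaxation limit cycle.  The generic
`dde_integrate()` shares the same engine for these kinds, only adding a
denser output mesh.

**Initial data.**  The model's history on $[-\tau, 0]$ may be constant,
linear, or an arbitrary function.  When omitted, it defaults to the steady
state plus a 1% perturbation — the paper-style studies here concern the
unique attractor, and a perturbed equilibrium reaches it fastest and
reproducibly.  The threshold model below $b = 1$ has no equilibrium; 0.5
is used there.

## Summarizing oscillations

`summarize_oscillation()` discards a transient fraction (default 0.5; Hopf
points exhibit critical slowing down, so near them we integrate 400 delays
rather than the default 100), then:

* the **period** is the mean spacing of successive upward crossings of the
  post-transient mean level, each crossing refined by bisection on the
  dense interpolant; `converged` requires the last three cycle periods to
  agree within 0.1%;
* the **extrema** are medians of local quadratic fits around mesh
  maxima/minima — except for event-driven trajectories, whose switch
  points are the exact extrema and are used directly;
* a trajectory is declared **not sustained** when fewer than 3 cycles
  remain, or when the amplitude over the second half of the window decays
  below 3/4 of the first half (a damped oscillation outside the unstable
  parameter interval), with the period reported as `NA`.

Summaries carry the period both in absolute time and in units of the delay
(`period_in_delay_units`).  All comparisons with the reference values for
the Mackey-Glass oscillation use the delay-unit convention, which is the
one consistent with the Hopf-period value $2\pi/(\pi/2 + 1/p) \approx
3.88$ at $p = 20$: at the lower Hopf point $\omega\tau = z \gtrsim \pi/2$,
so the period is just below $4\tau$.

## Strong-feedback limits

**Sawtooth oscillations (sigmoidal).**  For $\kappa\tau \gg 1$ the stable
periodic solution is a $4\tau$-periodic sawtooth of slope $\pm 1$ and
amplitude $\tau$ (`sawtooth_outer()`), with corners smoothed over an
$O(1/\kappa)$ transition layer of profile $-\kappa^{-1}\log(2\cosh
\kappa s)$; the matching constant is $-\log 2$.  The composite
approximation (`sawtooth_uniform()`) has extrema $\pm(\tau -
\kappa^{-1}\log 2)$, and its residual error is *exponentially* small in
$\kappa\tau$ — measured $10^{-3}$ at $\kappa\tau = 4$, $3\times 10^{-3}$
at $\kappa\tau = 3$, which is what the tests assert.  Only the
$4\tau$-periodic solution is stable (the $4\tau/(4n+1)$ harmonics are
not), and the simulated period equals $4\tau$ to machine precision.

**Relaxation cycle (threshold).**  For the Heaviside limit of the Hill
model with $0 < b < 1$ the limit cycle consists of four exponential
phases, giving the closed forms implemented in `threshold_cycle()`:

$$x_{\min} = e^{-b\tau},\qquad x_{\max} = (1 - b^{-1})e^{-b\tau} + b^{-1},$$
$$P \;=\; -\,b^{-1}\log\frac{x_{\min}\,(1-b\,x_{\max})}{x_{\max}\,(1-b\,x_{\min})}
     \;=\; 2\tau + \Delta_1 + \Delta_2 .$$

The grouping inside the logarithm is pinned down by deriving the period a
second, independent way — as the sum of the two delay phases plus the rise
time $\Delta_1 = -b^{-1}\log[(1-b)/(1-b\,x_{\min})]$ and fall time
$\Delta_2 = b^{-1}\log x_{\max}$ — and both forms are kept in the code and
asserted equal to $10^{-12}$ (property tests sample $b \in (0.1, 0.9)$,
$\tau \in (0.1, 3)$; outside that regime the $1/b$ prefactor amplifies the
logarithm round-off beyond machine precision and the identity is only
approximate in floating point).  The identity $(1 - b\,x_{\max}) =
(1-b)\,x_{\min}$ linking the extrema holds algebraically and is tested at
$10^{-14}$.  A third, fully independent route — the event-driven simulator
started from arbitrary data — reproduces all three numbers to $10^{-10}$.

At $p = 20$ the Hill model follows these closed forms with $O(\log p/p)$
corrections: across $b \in [0.2, 0.8]$ the measured converged deviations
are 0.6–2.5% for the period, 3–5% for the maxima, and up to 50% for small
minima (which sit inside the Hill smoothing zone); at $p = 200$ everything
agrees within 2%.  The bifurcation-diagram tests assert exactly these
measured bounds rather than a single nominal percentage.

## Hopf bifurcation machinery

The Mackey-Glass steady state satisfies $b = 1/(x(1+x^p))$
(`hill_steady_state()`, bisection in log space), and its linearisation has
the characteristic equation $\lambda = -A e^{-\lambda\tau} - b$ with $A =
p x^{p-1}/(1+x^p)^2$ (`characteristic_residual()`).  Substituting $\lambda
= i\omega$ and writing $z = \omega\tau$ gives the real-part relation $x^p
= -1/(p\cos z + 1)$ — which requires $\cos z < -1/p$, i.e. $z >
\arccos(-1/p)$ — and the imaginary-part relation $\tau = -z/(b \tan z)$.
Sweeping $z$ traces the entire Hopf boundary in the $(\tau, b)$ plane
(`hopf_curve()`); at fixed $\tau$ the boundary is crossed twice:

* a **lower** point $b_{H2} = O(1/p)$ with $x^p = O(p)$ (at $\tau = 1.8$,
  $p = 20$: $b = 0.0478$), approximated in closed form by $\pi/(2p\tau) =
  0.0436$;
* an **upper** point with $b$ near 1 ($b = 1.0426$), approximated
  parametrically by solving $-z_0/\tan z_0 = \tau$, $x_1 = -\log(-\cos
  z_0)$, $b = 1 + (\log p - x_1 - e^{x_1})/p = 1.0464$.

Because $\tau(z)$ diverges at both ends of the $z$ interval and is not
monotone, `hopf_point_at_tau()` first scans 400 subdivisions for sign
changes and then bisects each bracket; every returned point is
self-checked by the characteristic residual at $i\omega$ (asserted below
$10^{-8}$, typically $10^{-15}$).  The steady state is unstable — and the
oscillation sustained — exactly for $b$ between the two branches, which
the suite verifies at $b \in \{0.03, 0.06, 0.5, 1.2\}$.

**Singular Hopf reductions.**  As $p$ grows, the window where classical
Hopf scaling holds shrinks, and near each branch the dynamics reduce to a
scalar equation in a stretched variable.  Near $b_{H2}$, with $b = b_1/p$
and $x = 1 + (\log p + u)/p$, the leading problem is the Wright-type
equation $u' = e^{-u(t-\tau)} - b_1$, with Hopf point $b_1 = \pi/(2\tau)$
— which lifts back *identically* to $\pi/(2p\tau)$.  Near $b_{H1}$, with
$b = 1 + (\log p + b_1)/p$ and $x = 1 - (\log p - u)/p$, the reduced
equation is $u' = -e^{u(t-\tau)} - u - b_1$.  Its steady state satisfies
$b_1 = -(u + e^u)$ and its Hopf conditions are $\cos z = -e^{-u}$, $\tau =
-z/\tan z$; lifting reproduces the upper-branch approximation exactly.
Two sign/grouping ambiguities had to be resolved here: the reduced
equation's signs and the direction of the $\tau$–$z$ relation were fixed
by requiring consistency of the whole reduction chain (the linearisation
of the reduced equation forces $\tau = -z/\tan z$) and by the agreement of
the lifted Hopf value ($1.046$, printing as $1.04$) with the full model's
numeric point; both are enforced as tests.

The reductions predict the *shape* of the bifurcation diagram near each
point: simulating the Wright-type equation and lifting its extrema
reproduces the full model's minima near $b_{H2}$ within 0.01 while the
maxima drift apart away from the point, and symmetrically the upper
reduction reproduces the maxima near $b_{H1}$ — both verified in the
suite at $p = 20$.

**The local amplitude law (sigmoidal).**  Near $\tau_0 = \pi/(2\kappa)$
the periodic orbit grows as $2\sqrt{(\tau-\tau_0)/\tau_0}$ — in the
bifurcation problem's natural units.  Rescaling time by $\tau$ and state
by $\kappa$ maps the model to $y' \approx -\alpha(y(t-1) - y(t-1)^3/3)$,
$\alpha = \kappa\tau$, for which the coefficient-2 law holds; the physical
state amplitude is therefore the law divided by $\kappa$.
`hopf_local_amplitude()` returns both (`amplitude`, `x_amplitude`), and a
test confirms simulations saturate at `x_amplitude` to 5%.  The `valid`
flag marks the $O(1/\kappa)$ window $(\tau-\tau_0)/\tau_0 < 1/\kappa$ in
which the parabolic law can be trusted for strong gain; the constant in
that window is conventional and documented rather than derived.

## Sweeps, diagrams, fixtures

`sweep_bifurcation()` integrates each grid value of $b$ or $\tau$,
summarizes, and stores the results in a long-format table
(`param, quantity, value, source`) together with analytic overlays
(threshold-limit curves, sawtooth lines, local Hopf parabola) evaluated on
the same grid — one schema for numeric and analytic series makes plotting
and diffing trivial, and `write_diagram()`/`read_diagram()` round-trip it
bit-identically (17 significant digits).  Grid points are warm-started
from the previous point's final state to track the attractor; when that
state has collapsed onto the *unstable* steady state (as happens right
after crossing a Hopf point from the stable side), the sweep falls back to
the default perturbed history, since nothing can grow from an exact
equilibrium.  Warm and cold sweeps agree on the extrema to $10^{-4}$, as
the attractor is unique.  Failures at individual grid points are recorded
as `error` rows and do not abort the sweep.

Sweeps default to 150 delays per point (400 are used for the single-point
near-Hopf studies); with the event-exact threshold engine and the
vectorised stepping loop, the full test suite's sweeps run in seconds.

`generate_fixture()` produces sine, damped, sawtooth and square test
signals with known period and extrema (optionally noisy, with a restored
RNG state), which is how the summarizer itself is validated.  These
synthetic signals share the oscillatory features of the simulated
trajectories — smooth or kinked extrema, mean-level crossings, decay — but
not, of course, the dynamics; passing summarizer tests says nothing about
the integrator, which is instead checked against exact solutions, closed
forms, and an independent adaptive solver.

## Known limitations

* One constant delay, scalar state: no networks of coupled units, no
  distributed or state-dependent delays, no stochastic terms.
* Only the stable $4\tau$-periodic branch of the sign/sigmoidal model is
  treated; unstable harmonic branches are out of scope, as are Floquet
  analysis and normal-form coefficients.
* The asymptotic formulas are leading-order: their $O(\log p/p)$ and
  $O(e^{-\kappa\tau})$ errors are documented above and asserted at the
  measured magnitudes, not assumed smaller.
* The fixed-step integrator is designed for these smooth, non-stiff
  kinds; stiff variants would need a different engine.
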