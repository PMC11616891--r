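---
title: "Optimal feedforward impedance under task uncertainty: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal feedforward impedance under task uncertainty: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The control problem

`usooc` studies how a motor system should plan a *feedforward* (open-loop)
command when the task is uncertain. The plant is an Itô stochastic
differential equation

$$ dx_t = f(x_t, u(t), t;\, \xi)\,dt + G(x_t, u(t), t)\, dw_t, $$

with state $x \in \mathbb{R}^n$, a deterministic control trajectory
$u(t) \in \mathbb{R}^m$ fixed in advance, a random environmental parameter
$\xi \in \mathbb{R}^p$ (mean $\mu$, covariance $\Sigma$; for a disturbance
that occurs with probability $\alpha$, a Bernoulli variable with
$\mu = \alpha$, $\Sigma = \alpha(1-\alpha)$), internal motor noise through
the Wiener process $w$, and a random initial state $x_0 \sim (m_0, P_0)$.
The planner minimizes an expected cost
$E[\,q_f(x_T) + \int_0^T q(x_t, u(t), t)\,dt\,]$ with $q, q_f$ quadratic in
the state, over the admissible open-loop controls.

Because the control is open loop, the expected cost depends on the state
distribution only through its mean $m(t)$ and covariance $P(t)$: a quadratic
expectation rewrites as $m^\top Q m + \operatorname{tr}(Q P)$. The stochastic
problem therefore becomes a *deterministic* optimal control problem over the
moments. With $A(t) = \partial f/\partial x$ and
$C(t) = \partial f/\partial \xi$ evaluated along the mean (statistical
linearization — the mean itself always propagates through the full nonlinear
drift),

$$
\begin{aligned}
\dot m &= f(m, u, t; \mu), & m(0) &= m_0,\\
\dot P &= A P + P A^\top + G G^\top + C D^\top + D C^\top, & P(0) &= P_0,\\
\dot D &= A D + C \Sigma, & D(0) &= 0,
\end{aligned}
$$

where $D(t) = E[(x_t - m)(\xi - \mu)^\top]$ is the state–parameter
cross-covariance. For drifts affine in the state with state-independent
diffusion the moment propagation — and hence the whole reformulation — is
exact; for nonlinear drifts it is an approximation whose error vanishes as
$(P, D, \Sigma) \to 0$ (tested as a property on the pendulum model).

## How the covariance is represented

The package carries the covariance in the split form

$$ P(t) = P_1(t) + D(t)\, \Sigma^{-1} D(t)^\top, $$

where $P_1$ obeys $\dot P_1 = A P_1 + P_1 A^\top + G G^\top$ with
$P_1(0) = P_0$ (the motor-noise and initial-uncertainty part) and the
parameter-induced part is determined *exactly* by the cross-covariance: a
direct computation shows $\tfrac{d}{dt}\, D \Sigma^{-1} D^\top =
A (D\Sigma^{-1}D^\top) + (D\Sigma^{-1}D^\top) A^\top + C D^\top + D C^\top$
for any $A(t), C(t)$, which is the parameter-covariance equation with zero
initial condition. This identity has three practical consequences:

* the parameter-induced covariance (which has rank at most $p$ and therefore
  a structurally singular Cholesky factor) never needs its own matrix block
  or positivity constraints — it is positive semidefinite by construction;
* with a perfectly known initial state and no diffusion, the covariance
  block disappears entirely and the augmented state is just $(m, D)$, of
  dimension $n(p+1)$;
* the generic augmented dimension is $n\,(p + 1 + (n+1)/2)$: the mean, the
  packed symmetric factor block and the cross-covariance.

$P_1$ is propagated through its lower-triangular factor $L$ ($P_1 =
L L^\top$), so that positive definiteness along arbitrary solver iterates is
a set of box constraints on the factor diagonal (floored at $10^{-6}$). A
singular $P_0$ is floored to $P_0 + \varepsilon I$ before factorization,
with $\varepsilon = 10^{-5}$ when a diffusion term is present (the noise
inflates the covariance away from zero within the first grid interval
anyway, and the larger floor keeps the $L^{-1}$ terms of the factor dynamics
well conditioned) and $\varepsilon = 10^{-8}$ otherwise. Degenerate cases
reduce exactly: $\Sigma = 0$ drops $D$; a scalar state replaces the factor
by the exact box constraint $P_1 \ge 0$ where the factor dynamics would be
knife-edged (signal-dependent noise crossing zero).

## Transcription and the nonlinear program

The deterministic problem is transcribed by trapezoidal direct collocation:
states and controls live on a shared grid, the augmented dynamics enter as
defect equalities $z_{k+1} - z_k - \tfrac{h}{2}(F_k + F_{k+1}) = 0$, the
cost is evaluated by trapezoidal quadrature on the same grid, and control
bounds and factor floors are box constraints. Control trajectories are
piecewise linear on the grid. Default node counts: 101 for the 5-s
stabilization tasks, 76 for the 0.75-s arm reach, 51 for the 0.5-s wrist
reach — chosen so that doubling the grid moves the optimal cost by well
under 1% (tested).

No general equality-constrained nonlinear programming solver is available
to this package, so it ships its own sequential quadratic programming
method:

* one sparse, symmetrically equilibrated KKT factorization per iteration
  (`Matrix`), with the constraint Jacobian assembled analytically from
  per-node finite-difference Jacobians of the augmented right-hand side;
* the exact Hessian of the Lagrangian: analytic second derivatives of the
  quadratic mean/covariance cost (including through the factor
  parameterization) plus a per-node finite-difference contraction of the
  defect curvature with the multipliers;
* an $\ell_1$ merit function with a nonmonotone line search and a
  second-order correction step; an elastic penalty fallback when the
  linearized constraints are inconsistent with the working set;
* box constraints by active-set pinning with batch re-pinning inside the
  subproblem, multiplier-sign releases, and a least-squares multiplier
  refresh in the convergence test;
* a linear effort tie-break of $10^{-6}$ on lower-bounded control channels:
  quadratic effort has zero gradient at a resting muscle, which would leave
  the bound multipliers of inactive redundant actuators degenerate.

Convergence is declared at feasibility $10^{-8}$ and relative first-order
optimality $10^{-6}$ (both configurable), or when the iterate is feasible,
the objective is numerically stationary and the dual residual is within two
orders of the optimality target — the finite-difference constraint
Jacobians floor the attainable dual precision on some models.

Hard instances are solved by continuation, never from scratch: warm starts
across the disturbance-probability grid (with a cold restart and a
simpler-instance fallback when a warm start lands in the wrong basin),
a cost-weight homotopy for the stabilization task with initial-state
uncertainty, a noise-magnitude ladder for signal-dependent noise (the wrist
model ramps its multiplicative noise in three steps; the bilinear
stabilization model with multiplicative noise warm-starts from its
noise-free counterpart), and a deterministic-reach first stage for the arm.
The initial-state-uncertainty stabilization case additionally uses a
power-graded time grid: its optimal stiffness has a genuine boundary layer
(it starts near 70 and decays on a \~10 ms scale, confirmed against an
independent two-point boundary-value oracle), which a uniform grid cannot
resolve — on a uniform grid the transcription admits a spurious one-node
impulse ($k_1 = 2/h$) that annihilates the covariance in a single step.

## The shipped models

**Bilinear stabilization.** Scalar state, $\dot x = f - k x + \xi$ with net
force $f$ and stiffness $k \ge 0$, Bernoulli disturbance, cost
$E[q_f x(T)^2 + \int f^2 + k^2 + q x^2]$ with $q = q_f = 10^4$, $T = 5$ s,
terminal mean constraint $E[x(T)] = 0$. Optionally a control-multiplicative
diffusion $0.1k + 0.1f$. Its affine structure makes the moment reformulation
exact, so Monte-Carlo simulation of the original system is a sharp oracle.

**Inverted-pendulum forearm.** Upright hold against gravity
($k_g = 10.754$ N·m, $I = 0.337$ kg·m²) with an antagonist muscle pair:
net torque $k_n(u_1 - u_2)$, joint stiffness $k_s(u_1 + u_2)$, additive
motor noise $\sigma_a = 0.1$, a 1-N·m Bernoulli torque, state weights
$\mathrm{diag}(10^4, 10^3)$. At the upright posture stability requires the
muscle stiffness to exceed the gravity stiffness, which is why the solved
stiffness always sits above $k_g$ and why cold starts use a holding
co-contraction well above $k_g/k_s$.

**Planar 6-muscle arm.** Two-link reach, 25 cm forward in 750 ms, six
Kelvin–Voigt muscles through a constant moment-arm matrix, a lateral force
field $1.5\,\xi\,\dot y$ gated by the Bernoulli parameter, additive torque
noise, and a cost mixing effort, Cartesian acceleration and terminal
endpoint variance ($10^4 \operatorname{tr}(J P_\theta J^\top)$). Its
inertial and muscle constants are documented package defaults of a standard
human arm — approximations, so every claim made about this model is
qualitative (shape and ordering), never value-level. The arm's redundant
bounded actuation also makes its nonlinear program the hardest of the four;
the packaged solver reliably reaches near-feasibility but does not reliably
polish it to full optimality, and the tests assert exactly that.

**Wrist reach.** Single joint ($I = 0.01$ kg·m², $b = 0.05$ N·m·s/rad) with
first-order muscle activations ($\rho = 40$ ms) and activation-scaled
viscoelastic torques around a minimum-jerk reference
($k_n = 15$ N·m, $k_s = 15$ N·m/rad, $k_d = 1.5$ N·m·s/rad); a sigmoidal
external torque (plateau 0.75 N·m, 5–95% rise \~0.5 s) ramps up at 80% of
the movement, gated by the Bernoulli parameter; additive
($\sigma_a = 2\times 10^{-4}$) and signal-dependent ($\sigma_m = 0.02$)
noise act on the activation rates — the percentages are read as fractions
in activation-rate units. The movement duration defaults to 0.5 s, the
protocol's minimum valid duration and the mean movement time under the
always-on disturbance. The diffusion uses one independent Wiener channel
per additive and per signal-dependent term (four channels), so the two
activations carry uncorrelated noise.

## Monte-Carlo validation and the copies oracle

`simulate_trials()` integrates the *original* uncertain system by
Euler–Maruyama under a fixed control: the parameter is drawn from its
discrete support when one is declared (a Gaussian with the specified
moments otherwise, announced with a message), the initial state from
$N(m_0, P_0)$, and each trial gets independent Wiener increments. The
default step is a tenth of the control grid spacing; moment-matching tests
use a finer step because the weak-order-1 discretization bias must stay
inside the sampling band they assert. At the probability one half the two
Bernoulli scenario clusters produce identical squared deviations, so the
standard error of second-moment estimators degenerates — sharp
moment-matching checks therefore use an asymmetric probability.

For discrete parameters with a deterministic start and no diffusion,
`s_copies_expand()` builds the exact scenario reformulation: one copy of
the dynamics per support value, a single shared control, and the
probability-weighted sum of per-copy costs. For affine systems its optimal
cost must agree with the moment-augmentation path to within transcription
rounding; this dual-route agreement is one of the package's acceptance
properties.

The simulated wrist success criterion is a reconstruction (the experimental
protocol defines success through target geometry, timing and holding, which
an open-loop simulation cannot reproduce in full): a trial succeeds when the
angle never overshoots beyond the target window and lies within 0.076 rad of
the target — a 3-cm window at the cohort's mean hand length of 19.7 cm —
when evaluated 100 ms after the movement ends. That settling window is the
time scale on which an open-loop criterion is informative: at the movement
end itself the late disturbance has barely acted (success is ~0.99 at every
probability), while holds of a quarter second or more fail even undisturbed
trials, because holding a target against a ramping torque without feedback
is precisely what the model excludes. The criterion is configurable and
recorded with every result.

## Summary metrics

Co-contraction of an antagonist pair is the sum of its activation traces
and coactivation their pointwise minimum; under activation-scaled
viscoelastic muscles the sum is proportional to joint stiffness. "Mean"
stiffness is the trapezoidal time average over the full horizon. For the
arm, stiffness is the trace of the joint stiffness matrix
$M_a\,\mathrm{diag}(u_i k_e)\,M_a^\top$, time-averaged per probability
before any cross-probability fitting. Probability sweeps run on
Chebyshev-extrema grids, which sample the edges of $[0, 1]$ densely — the
uncertainty–stiffness curve is steepest there. The uncertainty–stiffness
relationship is summarized by a least-squares fit of
$y = a \log(x + c) + b$ with $c > 0$ profiled out; $c$ is fitted rather
than fixed so that zero uncertainty stays admissible, and the fit is
compared against the best affine fit so a "no log advantage" outcome is
visible. The co-contraction index CI integrates the summed antagonist
traces over the 170-ms pre-reflex window from 150 ms before to 20 ms after
the disturbance onset, normalized by the window length; nCI divides by the
movement's peak deceleration. On simulated data the muscle inputs (wrist:
the activation states) stand in for processed EMG — a modeling
identification, not a claim about real recordings.

## What the synthetic conditions do and do not show

The generators reproduce the study conditions: printed physical constants,
noise magnitudes, horizons, weights and disturbance parameters. They do not
emulate reflex or voluntary feedback corrections (the framework is
deliberately open loop), trial-to-trial learning or adaptation dynamics,
EMG measurement noise and filtering, or physiological muscle nonlinearities
beyond the activation-scaled viscoelastic law. Passing tests therefore
certify the mathematics of the moment propagation, the optimizer and the
predicted orderings (stiffness and co-contraction peaking at intermediate
disturbance probabilities), not quantitative agreement with any particular
recorded data set.

## Known limitations

* The packaged SQP is robust on the scalar and single-joint models but the
  arm's redundant-actuation program needs an industrial interior-point
  solver for full convergence; arm results should be treated as
  qualitative.
* Time-varying state weights are not supported (time-varying *references*
  are) — constant weights with a reference cover all shipped analyses.
* Cross-covariance never enters costs; only the mean and covariance do.
* Continuous parameter distributions are used through their first two
  moments only; exact-scenario validation requires a discrete support.
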