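# usooc

Uncertain stochastic optimal open-loop control for neuromechanical systems.

## The problem

When a motor task is uncertain — a perturbation that occurs on some trials
and not on others — pure feedback control is often too slow to save the
movement, and the nervous system instead prepares *feedforward*: it
co-contracts antagonist muscles, raising joint stiffness in advance.
`usooc` implements the computational theory behind this observation. The
plant is an Itô stochastic differential equation

    dx = f(x, u(t), t; xi) dt + G(x, u(t), t) dw,

with a deterministic open-loop control `u(t)`, a random environmental
parameter `xi` (for a disturbance of probability `alpha`, a Bernoulli
variable with mean `alpha` and variance `alpha (1 - alpha)` — the task
uncertainty), internal motor noise `w`, and a random initial state. The
planner minimizes an expected quadratic cost
`E[qf(x(T)) + ∫ q(x, u, t) dt]`.

Because the control is open loop, the expected cost depends only on the
state mean `m(t)`, covariance `P(t)` and state–parameter cross-covariance
`D(t)`, which obey the deterministic moment equations

    m' = f(m, u, t; mu)
    P' = A P + P A' + G G' + C D' + D C'
    D' = A D + C Sigma        (A = df/dx, C = df/dxi at the mean)

— exact for state-affine drifts, a statistical linearization otherwise. The
package converts problems into this augmented deterministic form (carrying
the covariance as `P = L L' + D Sigma^-1 D'` with a triangular factor for
the noise-fed part), transcribes them by trapezoidal direct collocation,
solves the resulting nonlinear program with a built-in sparse SQP method,
validates the predicted moments by Euler–Maruyama Monte-Carlo simulation of
the original system, and computes the field's impedance summaries:
stiffness, co-contraction (sum of antagonist activations), coactivation
(their minimum), Chebyshev-grid probability sweeps, logarithmic
uncertainty–stiffness fits, and pre-disturbance co-contraction indices
(CI, nCI).

Four models ship with their published constants: a bilinear stabilization
task (`make_toy_problem`), an inverted-pendulum forearm held against
gravity (`make_pendulum_problem`), a planar two-link six-muscle arm reach
(`make_arm_problem`; qualitative constants), and a wrist reach with
first-order muscle activations and a late sigmoidal disturbance
(`make_wrist_problem`).

## Worked example

Solve the stabilization task at disturbance probability one half, then sweep
the probability on a Chebyshev grid:

```r
library(usooc)

prob <- make_toy_problem(alpha = 0.5)
sol  <- solve_usooc(prob)
glance(sol)
#> # A tibble: 1 × 6
#>    cost status    iterations feasibility optimality nodes
#>   <dbl> <chr>          <dbl>       <dbl>      <dbl> <int>
#> 1  519. converged         13    3.32e-10   1.77e-11   101

sw <- sweep_alpha(make_toy_problem, chebyshev_alpha_grid(10))
round(sw$mean_stiffness, 2)
#> [1] 0.00 3.89 5.41 6.37 6.91 7.09 6.91 6.37 5.41 3.89 0.00
```

The optimal cost is about 519 and the time-averaged optimal stiffness rises
from exactly zero at the certainty endpoints (`alpha` 0 or 1, where the
disturbance is perfectly predictable and stiffness is wasted effort) to
about 7.1 at `alpha = 0.5`, the maximally uncertain task — symmetric in
`alpha` against `1 - alpha` because the moment dynamics depend on the
disturbance only through its variance. Fitting
`log_fit(sw$uncertainty, sw$mean_stiffness)` summarizes the steep rise at
low uncertainty followed by a gentler increase. `autoplot(sol)` and
`autoplot(sw)` draw the trajectories and the sweep; `simulate_trials()` and
`empirical_moments()` check any solution against Monte-Carlo simulation of
the original stochastic system.

A thin command-line interface wraps the same functions:

    Rscript inst/cli/usooc.R solve --model toy --alpha 0.5 --out results/
    Rscript inst/cli/usooc.R sweep --model pendulum --cheb-order 10 --out results/

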