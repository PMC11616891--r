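#' Bilinear stabilization model ("toy" problem)
#'
#' Scalar state with control `u = (f, k)`: a net force and a nonnegative
#' stiffness, drift `x' = f - k x + xi`, where `xi` is a Bernoulli disturbance
#' of probability `alpha`. The expected cost is
#' `E[qf x(T)^2 + int (f^2 + k^2 + q x^2) dt]` subject to the terminal mean
#' constraint `E[x(T)] = 0`. Optionally a control-multiplicative diffusion
#' `0.1 k + 0.1 f` models internal motor noise.
#'
#' @param alpha disturbance probability in `[0, 1]`.
#' @param horizon horizon T in seconds.
#' @param q,qf running and terminal state weights (`qf > 0`, `q >= 1`).
#' @param multiplicative_noise add the diffusion term `0.1 k + 0.1 f`.
#' @param P0 initial state variance (0 for a perfectly known start).
#' @return a validated `usooc_problem`.
#' @export
make_toy_problem <- function(alpha, horizon = 5, q = 1e4, qf = 1e4,
                             multiplicative_noise = FALSE, P0 = 0) {
  stopifnot(horizon > 0, qf > 0, q >= 1)
  drift <- function(x, u, t, xi) u[1] - u[2] * x + xi
  diffusion <- if (multiplicative_noise) {
    function(x, u, t) matrix(0.1 * u[2] + 0.1 * u[1], 1, 1)
  } else NULL
  prob <- uncertain_control_problem(
    drift = drift,
    diffusion = diffusion,
    xi = bernoulli_moments(alpha),
    init = initial_state(0, P0),
    horizon = horizon,
    cost = quadratic_cost(R = diag(2), Q = matrix(q), Qf = matrix(qf)),
    n = 1, m = 2,
    jac_x = function(x, u, t, xi) matrix(-u[2], 1, 1),
    jac_xi = function(x, u, t, xi) matrix(1, 1, 1),
    terminal_mean = list(idx = 1, value = 0),
    control_bounds = list(lower = c(-Inf, 0), upper = c(Inf, Inf)),
    affine_in_state = TRUE,
    diffusion_state_independent = TRUE,
    vectorized = TRUE,
    metrics = list(
      stiffness = function(U, M) U[2, ],
      net = function(U, M) U[1, ],
      activations = function(U, M) U,
      pairs = NULL
    ),
    name = sprintf("toy stabilization (alpha = %g)", alpha)
  )
  prob$alpha <- alpha
  prob$default_N <- 101
  validate_problem(prob)
}

#' Inverted-pendulum forearm model
#'
#' Single-joint forearm held upright against gravity by an antagonist muscle
#' pair with activation-scaled viscoelasticity: net torque `kn (u1 - u2)`,
#' joint stiffness `ks (u1 + u2)`, gravity torque `kg sin(theta)`, viscous
#' damping `b`, plus a Bernoulli external torque of `disturbance` N.m and an
#' additive motor noise of magnitude `sigma_a` on the acceleration row. The
#' task is a 5-s upright hold penalizing deviations of angle and velocity.
#'
#' @param alpha probability of the external torque.
#' @param horizon horizon in seconds.
#' @param disturbance external torque magnitude (N.m).
#' @param sigma_a additive noise magnitude.
#' @param k_n,k_s,k_g,b,inertia physical constants (N.m, N.m/rad, N.m,
#'   N.m.s/rad, kg.m^2).
#' @param P0 initial state covariance (scalar multiple of the identity).
#' @return a validated `usooc_problem`.
#' @export
make_pendulum_problem <- function(alpha, horizon = 5, disturbance = 1,
                                  sigma_a = 0.1, k_n = 1, k_s = 1,
                                  k_g = 10.754, b = 1, inertia = 0.337,
                                  P0 = 1e-5) {
  xi <- random_parameter(
    mu = alpha * disturbance,
    sigma = alpha * (1 - alpha) * disturbance^2,
    support = list(list(value = 0, prob = 1 - alpha),
                   list(value = disturbance, prob = alpha))
  )
  drift <- function(x, u, t, xi) {
    if (is.matrix(x)) {
      th <- x[1, ]; om <- x[2, ]
      xiv <- if (is.matrix(xi)) xi[1, ] else xi
      rbind(om, (k_n * (u[1] - u[2]) - k_s * (u[1] + u[2]) * th +
                   k_g * sin(th) - b * om + xiv) / inertia)
    } else {
      c(x[2], (k_n * (u[1] - u[2]) - k_s * (u[1] + u[2]) * x[1] +
                 k_g * sin(x[1]) - b * x[2] + xi) / inertia)
    }
  }
  prob <- uncertain_control_problem(
    drift = drift,
    diffusion = function(x, u, t) matrix(c(0, sigma_a), 2, 1),
    xi = xi,
    init = initial_state(c(0, 0), P0),
    horizon = horizon,
    cost = quadratic_cost(R = diag(2), Q = diag(c(1e4, 1e3)),
                          Qf = diag(c(1e4, 1e3))),
    n = 2, m = 2,
    jac_x = function(x, u, t, xi) {
      matrix(c(0, (-k_s * (u[1] + u[2]) + k_g * cos(x[1])) / inertia,
               1, -b / inertia), 2, 2)
    },
    jac_xi = function(x, u, t, xi) matrix(c(0, 1 / inertia), 2, 1),
    control_bounds = list(lower = c(0, 0), upper = c(Inf, Inf)),
    affine_in_state = FALSE,
    diffusion_state_independent = TRUE,
    vectorized = TRUE,
    metrics = list(
      stiffness = function(U, M) k_s * (U[1, ] + U[2, ]),
      net = function(U, M) k_n * (U[1, ] - U[2, ]),
      activations = function(U, M) U,
      pairs = list(c(1, 2))
    ),
    name = sprintf("inverted-pendulum forearm (alpha = %g)", alpha)
  )
  prob$alpha <- alpha
  prob$default_N <- 101
  # cold-start holding control: co-contraction well above the gravity
  # stiffness, in the basin where the covariance response is well-conditioned
  prob$guess_control <- rep(1.2 * k_g / k_s, 2)
  validate_problem(prob)
}

#' Sigmoidal disturbance torque
#'
#' `tau_e(t) = tau_max / (1 + 2 exp(-gamma (t - sigma)))^2`: monotone
#' nondecreasing, plateau `tau_max` as `t` grows; with the default constants
#' the 5\%-to-95\% rise takes about half a second.
#'
#' @param t time in seconds (vectorized).
#' @param tau_max plateau torque (N.m).
#' @param gamma rise-rate constant (1/s).
#' @param sigma time offset (s).
#' @return torque in N.m.
#' @export
sigmoid_torque <- function(t, tau_max = 0.75, gamma = 9.9903, sigma = 0.0652) {
  tau_max / (1 + 2 * exp(-gamma * (t - sigma)))^2
}

#' Minimum-jerk reference trajectory
#'
#' Fifth-order polynomial between `theta0` and `thetaT` with zero boundary
#' velocity and acceleration; times outside `[0, T]` clamp to the endpoint
#' values (with zero velocity).
#'
#' @param theta0,thetaT boundary positions.
#' @param T movement duration (s).
#' @param t evaluation times (vectorized).
#' @return list with `position` and `velocity` vectors.
#' @export
minimum_jerk_reference <- function(theta0, thetaT, T, t) {
  s <- pmin(pmax(t / T, 0), 1)
  d <- thetaT - theta0
  list(position = theta0 + d * (10 * s^3 - 15 * s^4 + 6 * s^5),
       velocity = d * (30 * s^2 - 60 * s^3 + 30 * s^4) / T)
}

#' Wrist reaching model with first-order muscle activation dynamics
#'
#' Single-joint wrist flexion from `-pi/6` to `pi/6` rad driven by an
#' antagonist muscle pair with activation states `a1, a2` (first-order lag of
#' the inputs `u1, u2` with time constant `rho`). Muscle torques follow an
#' activation-scaled viscoelastic law around a minimum-jerk reference:
#' `tau1 = a1 (kn - ks (theta - theta_r) - kd (dtheta - dtheta_r))` and
#' symmetrically for the extensor. A sigmoidal external torque, gated by a
#' Bernoulli variable of probability `alpha`, ramps up at `onset_frac` of the
#' movement in the movement direction. The diffusion carries additive
#' (`sigma_a`) and signal-dependent (`sigma_m u_i`) noise on the activation
#' rates.
#'
#' @param alpha disturbance probability.
#' @param horizon movement duration T in seconds.
#' @param inertia,b wrist inertia (kg.m^2) and viscosity (N.m.s/rad).
#' @param rho muscle activation time constant (s).
#' @param k_n,k_s,k_d muscle torque constants (N.m, N.m/rad, N.m.s/rad).
#' @param sigma_a,sigma_m additive and multiplicative noise magnitudes
#'   (fractions, in activation-rate units).
#' @param tau_max,gamma,sigma_t sigmoidal disturbance parameters
#'   (see [sigmoid_torque()]).
#' @param onset_frac disturbance onset as a fraction of the horizon.
#' @param theta0,thetaT start and target angles (rad).
#' @return a validated `usooc_problem`.
#' @export
make_wrist_problem <- function(alpha, horizon = 0.5, inertia = 0.01, b = 0.05,
                               rho = 0.04, k_n = 15, k_s = 15, k_d = 1.5,
                               sigma_a = 2e-4, sigma_m = 0.02,
                               tau_max = 0.75, gamma = 9.9903,
                               sigma_t = 0.0652, onset_frac = 0.8,
                               theta0 = -pi / 6, thetaT = pi / 6) {
  ref <- function(t) minimum_jerk_reference(theta0, thetaT, horizon, t)
  tau_p <- function(t) sigmoid_torque(t - onset_frac * horizon,
                                      tau_max = tau_max, gamma = gamma,
                                      sigma = sigma_t)
  drift <- function(x, u, t, xi) {
    r <- ref(t)
    if (is.matrix(x)) {
      th <- x[1, ]; om <- x[2, ]; a1 <- x[3, ]; a2 <- x[4, ]
      xiv <- if (is.matrix(xi)) xi[1, ] else xi
      dev <- k_s * (th - r$position) + k_d * (om - r$velocity)
      tau1 <- a1 * (k_n - dev)
      tau2 <- a2 * (k_n + dev)
      rbind(om, (tau1 - tau2 - b * om + tau_p(t) * xiv) / inertia,
            (u[1] - a1) / rho, (u[2] - a2) / rho)
    } else {
      dev <- k_s * (x[1] - r$position) + k_d * (x[2] - r$velocity)
      tau1 <- x[3] * (k_n - dev)
      tau2 <- x[4] * (k_n + dev)
      c(x[2], (tau1 - tau2 - b * x[2] + tau_p(t) * xi) / inertia,
        (u[1] - x[3]) / rho, (u[2] - x[4]) / rho)
    }
  }
  jac_x <- function(x, u, t, xi) {
    r <- ref(t)
    dev <- k_s * (x[1] - r$position) + k_d * (x[2] - r$velocity)
    asum <- x[3] + x[4]
    matrix(c(
      0, -k_s * asum / inertia, 0, 0,
      1, (-k_d * asum - b) / inertia, 0, 0,
      0, (k_n - dev) / inertia, -1 / rho, 0,
      0, -(k_n + dev) / inertia, 0, -1 / rho
    ), 4, 4)
  }
  diffusion <- function(x, u, t) {
    G <- matrix(0, 4, 4)
    G[3, 1] <- sigma_a / rho; G[3, 2] <- sigma_m * u[1] / rho
    G[4, 3] <- sigma_a / rho; G[4, 4] <- sigma_m * u[2] / rho
    G
  }
  prob <- uncertain_control_problem(
    drift = drift,
    diffusion = diffusion,
    xi = bernoulli_moments(alpha),
    init = initial_state(c(theta0, 0, 1e-4, 1e-4), 1e-5),
    horizon = horizon,
    cost = quadratic_cost(R = diag(2), Qf = diag(c(1, 0.1, 0, 0)),
                          terminal_reference = c(thetaT, 0, 0, 0)),
    n = 4, m = 2,
    jac_x = jac_x,
    jac_xi = function(x, u, t, xi) matrix(c(0, tau_p(t) / inertia, 0, 0), 4, 1),
    control_bounds = list(lower = c(0, 0), upper = c(1, 1)),
    affine_in_state = FALSE,
    diffusion_state_independent = TRUE,
    vectorized = TRUE,
    metrics = list(
      stiffness = function(U, M) k_s * (M[3, ] + M[4, ]),
      net = function(U, M) k_n * (M[3, ] - M[4, ]),
      activations = function(U, M) M[3:4, , drop = FALSE],
      pairs = list(c(1, 2))
    ),
    name = sprintf("wrist reaching (alpha = %g)", alpha)
  )
  prob$alpha <- alpha
  prob$default_N <- 51
  # cold start: moderate co-contraction makes the muscle pair a spring-damper
  # around the minimum-jerk reference, so the plant roughly tracks the reach
  prob$guess_control <- c(0.1, 0.1)
  # signal-dependent noise couples the controls into the covariance-factor
  # dynamics strongly; cold starts ramp it up from the additive-noise-only
  # instance (homotopy over sigma_m)
  if (sigma_m > 0) {
    rungs <- sigma_m * c(0, 0.4, 0.8)
    prob$homotopy <- function() {
      lapply(rungs, function(sm) {
        make_wrist_problem(alpha, horizon = horizon, inertia = inertia, b = b,
                           rho = rho, k_n = k_n, k_s = k_s, k_d = k_d,
                           sigma_a = sigma_a, sigma_m = sm, tau_max = tau_max,
                           gamma = gamma, sigma_t = sigma_t,
                           onset_frac = onset_frac, theta0 = theta0,
                           thetaT = thetaT)
      })
    }
  }
  prob$reference <- ref
  prob$disturbance_onset <- onset_frac * horizon
  prob$target <- thetaT
  validate_problem(prob)
}

#' Planar two-link six-muscle arm model
#'
#' Forward reach of 25 cm in 750 ms with a two-link arm (shoulder, elbow)
#' driven by six muscles (shoulder pair, elbow pair, biarticular pair) acting
#' through a constant moment-arm matrix. Each muscle is a Kelvin-Voigt
#' element whose elastic and viscous coefficients scale with its input, so
#' that the joint stiffness matrix is
#' `K = Ma diag(u_i k_e) Ma'`. The random disturbance is a lateral force
#' field `F = field_gain * xi * ydot` on the hand (a Bernoulli variable gates
#' a velocity-dependent field); internal noise is additive at torque level
#' (`M^-1 sigma_a` in the velocity rows). The cost mixes a terminal
#' endpoint-variance term `1e4 tr(J P_theta J')`, muscle effort and Cartesian
#' acceleration smoothness; the reach itself enters as a terminal constraint
#' on the mean state.
#'
#' The inertial and muscle constants are documented package defaults of a
#' standard human arm (approximations; analyses of this model should be
#' shape-level rather than value-level).
#'
#' @param alpha probability of the force field.
#' @param horizon movement duration (s).
#' @param sigma_a additive torque noise magnitude.
#' @param field_gain lateral force per unit forward hand velocity (N.s/m).
#' @param P0 initial state covariance (scalar multiple of the identity).
#' @param reach_distance forward reach distance (m).
#' @return a validated `usooc_problem`.
#' @export
make_arm_problem <- function(alpha, horizon = 0.75, sigma_a = 0.025,
                             field_gain = 1.5, P0 = 1e-6,
                             reach_distance = 0.25) {
  # two-link inertial parameters (upper arm / forearm+hand)
  l1 <- 0.30; l2 <- 0.33
  m2 <- 1.0; lc2 <- 0.16
  I1 <- 0.025; I2 <- 0.045
  a1c <- I1 + I2 + m2 * l1^2
  a2c <- m2 * l1 * lc2
  a3c <- I2
  # moment-arm matrix (m): shoulder pair, elbow pair, biarticular pair
  Ma <- matrix(c(0.040, 0, -0.040, 0, 0, 0.025, 0, -0.025,
                 0.028, 0.028, -0.035, -0.035), 2, 6)
  f0 <- 40     # N per unit activation
  ke <- 3000   # N/m elastic coefficient per unit activation
  be <- 60     # N.s/m viscous coefficient per unit activation

  hand_pos <- function(th) c(l1 * cos(th[1]) + l2 * cos(th[1] + th[2]),
                             l1 * sin(th[1]) + l2 * sin(th[1] + th[2]))
  jac_hand <- function(th) {
    s1 <- sin(th[1]); c1 <- cos(th[1])
    s12 <- sin(th[1] + th[2]); c12 <- cos(th[1] + th[2])
    matrix(c(-l1 * s1 - l2 * s12, l1 * c1 + l2 * c12,
             -l2 * s12, l2 * c12), 2, 2)
  }
  jac_hand_dot <- function(th, om) {
    c1 <- cos(th[1]); s1 <- sin(th[1])
    c12 <- cos(th[1] + th[2]); s12 <- sin(th[1] + th[2])
    o12 <- om[1] + om[2]
    matrix(c(-l1 * c1 * om[1] - l2 * c12 * o12,
             -l1 * s1 * om[1] - l2 * s12 * o12,
             -l2 * c12 * o12, -l2 * s12 * o12), 2, 2)
  }
  theta0 <- c(pi / 4, pi / 2)
  # inverse kinematics for the target: hand moved forward by reach_distance
  target_xy <- hand_pos(theta0) + c(0, reach_distance)
  ik <- stats::optim(theta0, function(th) sum((hand_pos(th) - target_xy)^2),
                     method = "BFGS", control = list(reltol = 1e-14))
  thetaT <- ik$par

  minv <- function(th) {
    c2 <- cos(th[2])
    m11 <- a1c + 2 * a2c * c2; m12 <- a3c + a2c * c2
    det <- m11 * a3c - m12^2
    matrix(c(a3c, -m12, -m12, m11), 2, 2) / det
  }
  accel <- function(th, om, u, xi) {
    s2 <- sin(th[2])
    cor <- a2c * s2 * c(-om[2] * (2 * om[1] + om[2]), om[1]^2)
    stretch <- drop(crossprod(Ma, th - theta0))
    dstretch <- drop(crossprod(Ma, om))
    Fm <- u * (f0 - ke * stretch - be * dstretch)
    tau_m <- drop(Ma %*% Fm)
    J <- jac_hand(th)
    ydot <- sum(J[2, ] * om)
    tau_p <- drop(t(J) %*% c(field_gain * xi * ydot, 0))
    drop(minv(th) %*% (tau_m - cor + tau_p))
  }
  drift <- function(x, u, t, xi) {
    th <- x[1:2]; om <- x[3:4]
    c(om, accel(th, om, u, xi))
  }
  diffusion <- if (sigma_a > 0) {
    function(x, u, t) rbind(matrix(0, 2, 2), minv(x[1:2]) * sigma_a)
  } else {
    NULL
  }
  jac_xi <- function(x, u, t, xi) {
    th <- x[1:2]; om <- x[3:4]
    J <- jac_hand(th)
    ydot <- sum(J[2, ] * om)
    matrix(c(0, 0, minv(th) %*% (t(J) %*% c(field_gain * ydot, 0))), 4, 1)
  }
  extra_running <- function(m, P, u, t) {
    th <- m[1:2]; om <- m[3:4]
    a <- jac_hand_dot(th, om) %*% om + jac_hand(th) %*% accel(th, om, u, alpha)
    0.5 * sum(a^2)
  }
  extra_terminal <- function(m, P) {
    J <- jac_hand(m[1:2])
    1e4 * sum(diag(J %*% P[1:2, 1:2] %*% t(J)))
  }
  prob <- uncertain_control_problem(
    drift = drift,
    diffusion = diffusion,
    xi = bernoulli_moments(alpha),
    init = initial_state(c(theta0, 0, 0), P0),
    horizon = horizon,
    cost = quadratic_cost(R = diag(6), extra_running = extra_running,
                          extra_terminal = extra_terminal),
    n = 4, m = 6,
    jac_xi = jac_xi,
    terminal_mean = list(idx = 1:4, value = c(thetaT, 0, 0)),
    control_bounds = list(lower = rep(0, 6), upper = rep(Inf, 6)),
    affine_in_state = FALSE,
    diffusion_state_independent = FALSE,
    vectorized = FALSE,
    metrics = list(
      stiffness = function(U, M) {
        vapply(seq_len(ncol(U)), function(k) {
          K <- Ma %*% (U[, k] * ke * t(Ma))
          sum(diag(K))
        }, numeric(1))
      },
      activations = function(U, M) U,
      pairs = list(c(1, 2), c(3, 4), c(5, 6))
    ),
    name = sprintf("planar 6-muscle arm reach (alpha = %g)", alpha)
  )
  prob$alpha <- alpha
  prob$default_N <- 76
  # cold starts solve the deterministic reach first, then switch the noise on
  if (alpha > 0 || sigma_a > 0) {
    prob$homotopy <- function() {
      stages <- list(make_arm_problem(0, horizon = horizon, sigma_a = 0,
                                      field_gain = field_gain, P0 = 0,
                                      reach_distance = reach_distance))
      if (alpha > 0) {
        stages <- c(stages, list(make_arm_problem(
          0, horizon = horizon, sigma_a = sigma_a, field_gain = field_gain,
          P0 = P0, reach_distance = reach_distance)))
      }
      stages
    }
  }
  prob$kinematics <- list(hand_pos = hand_pos, jac_hand = jac_hand,
                          theta0 = theta0, thetaT = thetaT)
  validate_problem(prob)
}
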