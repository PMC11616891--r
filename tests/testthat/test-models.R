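test_that("sigmoidal disturbance has the right plateau, midpoint and rise time", {
  expect_equal(sigmoid_torque(1e3), 0.75, tolerance = 1e-12)
  expect_equal(sigmoid_torque(0.0652), 0.75 / 9, tolerance = 1e-10)
  # monotone nondecreasing
  tt <- seq(-0.5, 1.5, 0.001)
  expect_true(all(diff(sigmoid_torque(tt)) >= 0))
  # 5% -> 95% crossing separation close to half a second
  t05 <- uniroot(function(t) sigmoid_torque(t) - 0.05 * 0.75, c(-1, 1))$root
  t95 <- uniroot(function(t) sigmoid_torque(t) - 0.95 * 0.75, c(-1, 2))$root
  expect_equal(t95 - t05, 0.5, tolerance = 0.025)
})

test_that("minimum-jerk reference hits its boundary and midpoint values", {
  th0 <- -pi / 6; thT <- pi / 6; T_ <- 0.5
  r0 <- minimum_jerk_reference(th0, thT, T_, 0)
  rT <- minimum_jerk_reference(th0, thT, T_, T_)
  rm <- minimum_jerk_reference(th0, thT, T_, T_ / 2)
  expect_equal(r0$position, th0); expect_equal(r0$velocity, 0)
  expect_equal(rT$position, thT); expect_equal(rT$velocity, 0)
  expect_equal(rm$position, (th0 + thT) / 2)
  expect_equal(rm$velocity, 1.875 * (thT - th0) / T_)
  # clamping outside the horizon
  rpre <- minimum_jerk_reference(th0, thT, T_, -1)
  rpost <- minimum_jerk_reference(th0, thT, T_, 2)
  expect_equal(rpre$position, th0); expect_equal(rpre$velocity, 0)
  expect_equal(rpost$position, thT); expect_equal(rpost$velocity, 0)
})

test_that("pendulum drift balances at the upright equilibrium", {
  prob <- make_pendulum_problem(0.5)
  for (u in c(0.2, 1, 6)) {
    d <- prob$drift(c(0, 0), c(u, u), 0, 0)
    expect_equal(d, c(0, 0), tolerance = 1e-12)
  }
  # odd symmetry: flipping angle/velocity/disturbance and swapping the
  # antagonists negates the drift
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(2, 0, 0.3); u <- runif(2, 0, 5); xi <- rnorm(1)
    d1 <- prob$drift(x, u, 0, xi)
    d2 <- prob$drift(-x, rev(u), 0, -xi)
    expect_equal(d2, -d1, tolerance = 1e-10)
  }
})

test_that("wrist muscle torques follow the activation-scaled viscoelastic law", {
  prob <- make_wrist_problem(0.5)
  inertia <- 0.01; b <- 0.05; k_n <- 15; k_s <- 15
  ref <- prob$reference(0.2)
  # on the reference: tau1 = a1 kn, tau2 = a2 kn
  x <- c(ref$position, ref$velocity, 0.3, 0.2)
  d <- prob$drift(x, c(0, 0), 0.2, 0)
  tau_net <- d[2] * inertia + b * ref$velocity
  expect_equal(tau_net, (0.3 - 0.2) * k_n, tolerance = 1e-10)

  # stiffness contribution at matched activations: d(tau1 - tau2)/dtheta = -2 a ks
  a <- 0.4
  dnet_dth <- fd_jac_oracle(function(th) {
    xx <- c(th, ref$velocity, a, a)
    prob$drift(xx, c(0, 0), 0.2, 0)[2] * inertia + b * ref$velocity
  }, ref$position)
  expect_equal(drop(dnet_dth), -2 * a * k_s, tolerance = 1e-5)

  # the disturbance ramp is negligible more than ~0.47 s before its plateau
  expect_lt(sigmoid_torque(-0.47), 0.01 * 0.75)
})

test_that("wrist drift is odd-symmetric about the reference", {
  prob <- make_wrist_problem(0.5)
  ref <- prob$reference(0.25)
  set.seed(4)
  for (i in 1:8) {
    dth <- rnorm(1, 0, 0.2); dom <- rnorm(1, 0, 0.5); a <- runif(2, 0, 0.5)
    x1 <- c(ref$position + dth, ref$velocity + dom, a[1], a[2])
    x2 <- c(ref$position - dth, ref$velocity - dom, a[2], a[1])
    d1 <- prob$drift(x1, c(0, 0), 0.25, 0)
    d2 <- prob$drift(x2, c(0, 0), 0.25, 0)
    # the net muscle+damping torque about the reference flips sign
    tau1 <- d1[2] * 0.01
    tau2 <- d2[2] * 0.01
    expect_equal(tau1 + tau2, -0.05 * 2 * ref$velocity, tolerance = 1e-10)
  }
})

test_that("Kelvin-Voigt torques vanish at zero activation", {
  wrist <- make_wrist_problem(0.3)
  d <- wrist$drift(c(0.1, 0.4, 0, 0), c(0, 0), 0.1, 0)
  expect_equal(d[2] * 0.01, -0.05 * 0.4, tolerance = 1e-12)  # damping only

  arm <- make_arm_problem(0.3)
  x <- c(pi / 4, pi / 2, 0.3, -0.2)
  d0 <- arm$drift(x, rep(0, 6), 0, 0)
  # with zero muscle input only Coriolis terms act; adding muscle input at
  # zero stretch changes the torque
  expect_true(all(is.finite(d0)))
  x_rest <- c(arm$kinematics$theta0, 0, 0)
  d_rest <- arm$drift(x_rest, rep(0, 6), 0, 0)
  expect_equal(d_rest, rep(0, 4), tolerance = 1e-12)
})

test_that("the arm force field is velocity-gated and maps through the Jacobian", {
  prob <- make_arm_problem(0.5)
  x_rest <- c(pi / 4, pi / 2, 0, 0)  # zero joint velocity => zero field
  expect_equal(prob$drift(x_rest, rep(0.1, 6), 0, 0),
               prob$drift(x_rest, rep(0.1, 6), 0, 5), tolerance = 1e-12)

  # moving: the parameter sensitivity equals M^-1 J' (gain * ydot, 0)
  x <- c(pi / 4, pi / 2, 0.5, 0.8)
  lin <- linearize(prob, x, rep(0.1, 6), 0)
  J <- prob$kinematics$jac_hand(x[1:2])
  ydot <- sum(J[2, ] * x[3:4])
  expect_gt(abs(ydot), 0.01)  # genuinely moving along y
  # finite-difference oracle on the drift's xi dependence
  C_fd <- fd_jac_oracle(function(xi) prob$drift(x, rep(0.1, 6), 0, xi),
                        prob$xi$mu)
  expect_equal(lin$C, C_fd, tolerance = 1e-6)
  # lateral force with positive ydot and xi > 0 accelerates the joints along
  # M^-1 J' (gain ydot, 0); verify the direction against the kinematic oracle
  dplus <- prob$drift(x, rep(0.1, 6), 0, 1)
  dzero <- prob$drift(x, rep(0.1, 6), 0, 0)
  acc_p <- (dplus - dzero)[3:4]        # = M^-1 tau_p
  tau_dir <- drop(t(J) %*% c(1.5 * ydot, 0))
  # M^-1 is positive definite, so the angle between acc_p and tau_p stays
  # acute; check the inner product sign and xi-linearity
  expect_gt(sum(acc_p * tau_dir), 0)
  d2 <- prob$drift(x, rep(0.1, 6), 0, 2)
  expect_equal((d2 - dzero)[3:4], 2 * acc_p, tolerance = 1e-9)
})

test_that("every factory output passes validation and its preset defaults", {
  for (prob in list(make_toy_problem(0.5), make_pendulum_problem(0.5),
                    make_wrist_problem(0.5), make_arm_problem(0.5))) {
    expect_true(prob$validated)
    expect_true(!is.null(prob$variant))
    expect_true(prob$default_N >= 10)
  }
})

test_that("arm transcription makes feasibility progress on a coarse grid", {
  # the arm ships as a qualitative model (its muscle constants are package
  # approximations); assert that transcription + solver reduce the defect
  # violation substantially from the cold start rather than full convergence
  prob <- make_arm_problem(0, sigma_a = 0, P0 = 0)
  prob$homotopy <- NULL
  aug <- build_augmented(prob)
  times <- seq(0, 0.75, length.out = 26)
  nlp <- transcribe(aug, times)
  U0 <- matrix(1e-3, 6, 26)
  Z0 <- matrix(aug$z0, aug$dim, 26)
  feas0 <- max(abs(nlp$cons_full(Z0, U0)))
  sol <- solve_usooc(prob, N = 26, control = list(maxit = 40, curv_every = 5))
  expect_lt(sol$feasibility, 1e-2)
  expect_lt(sol$feasibility, feas0 / 10)
  expect_true(all(is.finite(sol$U)))
})
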