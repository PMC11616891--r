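test_that("Bernoulli disturbance moments match the closed forms exactly", {
  for (a in c(0, 0.25, 0.5, 1)) {
    xi <- bernoulli_moments(a)
    expect_identical(xi$mu, a)
    expect_identical(drop(xi$sigma), a * (1 - a))
    probs <- vapply(xi$support, function(s) s$prob, numeric(1))
    vals <- vapply(xi$support, function(s) s$value, numeric(1))
    expect_equal(sum(probs), 1)
    # moments recomputed from the discrete support
    expect_equal(sum(probs * vals), a)
    expect_equal(sum(probs * (vals - a)^2), a * (1 - a))
  }
  expect_error(bernoulli_moments(-0.1), "probability")
  expect_error(bernoulli_moments(1.5), "probability")
})

test_that("random_parameter validates its support and covariance", {
  expect_error(random_parameter(0, matrix(-1)), "sigma")
  expect_error(
    random_parameter(0.5, 0.25,
                     support = list(list(value = 0, prob = 0.6),
                                    list(value = 1, prob = 0.6))),
    "sum to 1")
  expect_error(
    random_parameter(0.3, 0.25,
                     support = list(list(value = 0, prob = 0.5),
                                    list(value = 1, prob = 0.5))),
    "moments")
})

test_that("augmented dimension follows n(p+1+(n+1)/2), reducing to n(p+1)", {
  expect_equal(augmented_dimension(1, 1), 3)
  expect_equal(augmented_dimension(1, 1, deterministic_init = TRUE), 2)
  expect_equal(augmented_dimension(4, 1), 18)
  expect_equal(augmented_dimension(2, 1), 7)
})

test_that("augmented dimension matches the flattened state the builder produces", {
  # generic case: nonzero parameter covariance and initial covariance
  pend <- make_pendulum_problem(0.3)
  expect_equal(build_augmented(pend)$dim,
               augmented_dimension(pend$n, pend$p))
  wrist <- make_wrist_problem(0.5)
  expect_equal(build_augmented(wrist)$dim,
               augmented_dimension(wrist$n, wrist$p))
  # deterministic initial state: the reduced (m, D) form
  toy <- make_toy_problem(0.5)
  expect_equal(build_augmented(toy, reduced = TRUE)$dim,
               augmented_dimension(1, 1, deterministic_init = TRUE))
})

test_that("linearize returns hand-derived Jacobians on the shipped models", {
  toy <- make_toy_problem(0.4)
  lin <- linearize(toy, m = 0.3, u = c(0.5, 2), t = 1)
  expect_equal(drop(lin$A), -2)
  expect_equal(drop(lin$C), 1)

  pend <- make_pendulum_problem(0.2)
  lin <- linearize(pend, m = c(0, 0), u = c(0, 0), t = 0)
  expect_equal(lin$A[2, 1], 10.754 / 0.337, tolerance = 1e-10)
  expect_equal(lin$C[2, 1], 1 / 0.337, tolerance = 1e-10)

  # drift independent of the parameter gives C = 0
  noxi <- uncertain_control_problem(
    drift = function(x, u, t, xi) -x + u,
    xi = random_parameter(0, 1), init = initial_state(0),
    horizon = 1, cost = quadratic_cost(R = matrix(1)), n = 1, m = 1,
    affine_in_state = TRUE)
  expect_equal(drop(linearize(noxi, 0.2, 0.1, 0)$C), 0, tolerance = 1e-8)
})

test_that("analytic model Jacobians agree with finite differences at random probes", {
  set.seed(11)
  models <- list(
    toy = make_toy_problem(0.3),
    pendulum = make_pendulum_problem(0.4),
    wrist = make_wrist_problem(0.6),
    arm = make_arm_problem(0.2)
  )
  for (nm in names(models)) {
    prob <- models[[nm]]
    for (i in 1:25) {
      m <- prob$init$m0 + 0.3 * rnorm(prob$n)
      u <- pmin(pmax(runif(prob$m, 0.05, 0.6), prob$control_bounds$lower),
                prob$control_bounds$upper)
      t <- runif(1, 0, prob$horizon)
      lin <- linearize(prob, m, u, t)
      A_fd <- fd_jac_oracle(function(x) prob$drift(x, u, t, prob$xi$mu), m)
      C_fd <- fd_jac_oracle(function(xi) prob$drift(m, u, t, xi), prob$xi$mu)
      expect_lt(max(abs(lin$A - A_fd)), 1e-6 * max(1, max(abs(A_fd))))
      expect_lt(max(abs(lin$C - C_fd)), 1e-6 * max(1, max(abs(C_fd))))
    }
  }
})

test_that("validate_problem annotates the structural variant", {
  expect_equal(make_toy_problem(0.5)$variant, "affine_no_diff")
  expect_equal(make_toy_problem(0.5, multiplicative_noise = TRUE)$variant,
               "affine_diff")
  expect_equal(make_pendulum_problem(0.5)$variant, "general")
  expect_equal(make_wrist_problem(0.5)$variant, "general")
  expect_equal(make_arm_problem(0.5)$variant, "general")
})

test_that("validation errors name the offending field", {
  bad_sigma <- matrix(c(1, 2, 2, 1), 2, 2)  # eigenvalues 3, -1
  expect_error(random_parameter(c(0, 0), bad_sigma), "sigma")
  expect_error(initial_state(c(0, 0), bad_sigma), "p0")
  expect_error(quadratic_cost(R = matrix(0)), "positive definite")
  # declaring a nonlinear drift affine is caught by probing
  pend <- make_pendulum_problem(0.5)
  pend$affine_in_state <- TRUE
  pend$validated <- FALSE
  expect_error(validate_problem(pend), "affine")
})
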