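test_that("transcription layout and defect order behave as advertised", {
  prob <- make_toy_problem(0.5)
  aug <- build_augmented(prob)
  N <- 41
  times <- seq(0, 5, length.out = N)
  nlp <- transcribe(aug, times)
  # decision vector: states at nodes 2..N plus controls at every node
  expect_equal(nlp$nw, (N - 1) * aug$dim + N * prob$m)
  expect_equal(nlp$ncon, (N - 1) * aug$dim + 1)  # defects + terminal mean

  # a finely forward-integrated trajectory satisfies the defects to O(h^2)
  U <- rbind(rep(0.1, N), rep(0.6, N))
  Z <- propagate_augmented(aug, U, times, substeps = 16)
  cvec <- nlp$cons_full(Z, U)
  h <- diff(times)[1]
  expect_lt(max(abs(cvec[seq_len((N - 1) * aug$dim)])), 5 * h^2)

  # grid sanity checks
  expect_error(transcribe(aug, seq(0, 5, length.out = 5)), "at least 10")
  expect_error(transcribe(aug, rev(times)), "increasing")
})

test_that("the zero-uncertainty stabilization admits the zero solution", {
  prob <- make_toy_problem(0)
  aug <- build_augmented(prob)
  times <- seq(0, 5, length.out = 21)
  nlp <- transcribe(aug, times, tie_eps = 0)
  w0 <- nlp$w_pack(matrix(0, aug$dim, 21), matrix(0, 2, 21))
  expect_equal(max(abs(nlp$cons_full(matrix(0, aug$dim, 21), matrix(0, 2, 21)))), 0)
  expect_equal(nlp$obj_full(matrix(0, aug$dim, 21), matrix(0, 2, 21)), 0)
})

test_that("the solver reproduces the closed-form linear-quadratic optimum", {
  skip_if_not_installed("deSolve")
  # scalar system xdot = -x + u, J = qf x(T)^2 + int u^2 + q x^2, x(0) = 1.
  # Independent oracle: integrate the associated quadratic-gain equation
  # backwards; the optimal cost is s(0) x0^2.
  a <- -1; q <- 2; qf <- 1; T_ <- 2; x0 <- 1
  gain <- deSolve::ode(c(s = qf), seq(0, T_, 0.001), function(t, y, p) {
    list(2 * a * y + q - y^2)  # backward equation in s(T - t)
  }, NULL, rtol = 1e-12, atol = 1e-14)
  J_star <- tail(gain[, "s"], 1) * x0^2

  prob <- uncertain_control_problem(
    drift = function(x, u, t, xi) a * x + u,
    xi = random_parameter(0, 0),
    init = initial_state(x0),
    horizon = T_,
    cost = quadratic_cost(R = matrix(1), Q = matrix(q), Qf = matrix(qf)),
    n = 1, m = 1,
    jac_x = function(x, u, t, xi) matrix(a),
    jac_xi = function(x, u, t, xi) matrix(0),
    affine_in_state = TRUE, vectorized = TRUE, name = "LQ sanity")
  sol <- solve_usooc(prob, N = 201, control = list(maxit = 60))
  expect_equal(sol$status, "converged")
  expect_equal(sol$cost, J_star, tolerance = 1e-4)
})

test_that("solutions re-integrate: the collocated path is dynamically feasible", {
  sol <- cached_solve("toy05", solve_toy(0.5))
  expect_equal(sol$status, "converged")
  Zre <- propagate_augmented(sol$aug, sol$U, sol$times, substeps = 24)
  expect_lt(max(abs(Zre[, ncol(Zre)] - sol$Z[, ncol(sol$Z)])), 1e-3)
})

test_that("single-node stiffness perturbations never improve the cost", {
  # first-order optimality probe on the disturbance-certain instance: the
  # stiffness channel does not affect the terminal mean constraint at m = 0,
  # so perturbed controls stay feasible after re-integration
  sol <- cached_solve("toy1", solve_toy(1))
  expect_equal(sol$status, "converged")
  aug <- sol$aug
  base <- mean_cov_cost(aug, propagate_augmented(aug, sol$U, sol$times),
                        sol$U, sol$times)
  for (k in c(10, 40, 70, 101)) {
    U2 <- sol$U
    U2[2, k] <- U2[2, k] + 0.01  # k >= 0; upward perturbation
    J2 <- mean_cov_cost(aug, propagate_augmented(aug, U2, sol$times),
                        U2, sol$times)
    expect_gte(J2, base - 1e-10)
  }
})

test_that("continuation with a single instance equals the plain solve", {
  sols <- continuation_solve(list(make_toy_problem(0.5)), N = 101)
  plain <- cached_solve("toy05", solve_toy(0.5))
  expect_equal(sols[[1]]$cost, plain$cost, tolerance = 1e-9)
})

test_that("continuation shows no hysteresis on the stabilization sweep", {
  alphas <- c(0.2, 0.5, 0.8)
  fwd <- continuation_solve(function(a) make_toy_problem(a), alphas, N = 61)
  bwd <- continuation_solve(function(a) make_toy_problem(a), rev(alphas), N = 61)
  cf <- vapply(fwd, function(s) s$cost, numeric(1))
  cb <- rev(vapply(bwd, function(s) s$cost, numeric(1)))
  expect_equal(cf, cb, tolerance = 1e-4)
})

test_that("non-convergence is reported through the status, not an error", {
  prob <- make_toy_problem(0.5)
  sol <- solve_usooc(prob, N = 41, control = list(maxit = 2))
  expect_true(sol$status %in% c("max_iter", "infeasible"))
  expect_type(sol$solver_log, "character")
})

test_that("tidiers summarize solutions as tibbles", {
  sol <- cached_solve("toy05", solve_toy(0.5))
  td <- tidy(sol)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("t", "u_1", "u_2", "m_1", "stiffness") %in% names(td)))
  gl <- glance(sol)
  expect_equal(gl$status, "converged")
  expect_equal(gl$nodes, 101)
  p <- autoplot(sol)
  expect_s3_class(p, "ggplot")
})
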