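test_that("ensembles are bit-identical under a fixed seed", {
  prob <- make_toy_problem(0.5)
  ctrl <- list(U = rbind(rep(0, 21), rep(1, 21)),
               times = seq(0, 5, length.out = 21))
  e1 <- simulate_trials(prob, ctrl, trials = 200, seed = 7)
  e2 <- simulate_trials(prob, ctrl, trials = 200, seed = 7)
  expect_identical(e1$states, e2$states)
  expect_identical(e1$xi, e2$xi)
  e3 <- simulate_trials(prob, ctrl, trials = 200, seed = 8)
  expect_false(identical(e1$states, e3$states))
})

test_that("without any noise every trial equals the deterministic solution", {
  prob <- make_toy_problem(0)  # Sigma = 0, P0 = 0, no diffusion
  times <- seq(0, 5, length.out = 21)
  ctrl <- list(U = rbind(rep(0.3, 21), rep(0.5, 21)), times = times)
  ens <- simulate_trials(prob, ctrl, trials = 20, seed = 1, dt = 0.005)
  spread <- apply(ens$states[1, , ], 1, function(v) diff(range(v)))
  expect_equal(max(spread), 0)
  # and the common trajectory matches the propagated mean to dt accuracy
  aug <- build_augmented(prob)
  Z <- propagate_augmented(aug, ctrl$U, times)
  expect_lt(max(abs(ens$states[1, , 1] - Z[1, ])), 5e-3)
})

test_that("empirical moment estimators behave at the degenerate corners", {
  prob <- make_toy_problem(0)
  ctrl <- list(U = rbind(rep(0.3, 11), rep(0.5, 11)),
               times = seq(0, 5, length.out = 11))
  ens <- simulate_trials(prob, ctrl, trials = 50, seed = 2)
  mom <- empirical_moments(ens)
  expect_equal(max(abs(mom$P)), 0)  # identical trajectories
  expect_equal(max(abs(mom$D)), 0)  # deterministic parameter
  ens1 <- ens; ens1$trials <- 1; ens1$states <- ens$states[, , 1, drop = FALSE]
  expect_error(empirical_moments(ens1), "2 trials")
})

test_that("sampled cross-covariance reproduces the deterministic-start identity", {
  prob <- make_toy_problem(0.5)
  times <- seq(0, 5, length.out = 26)
  ctrl <- list(U = rbind(rep(0.1, 26), rep(0.9, 26)), times = times)
  ens <- simulate_trials(prob, ctrl, trials = 5000, seed = 5)
  mom <- empirical_moments(ens)
  k <- 26
  Phat <- mom$P[1, 1, k]
  Dhat <- mom$D[1, 1, k]
  expect_equal(Dhat^2 / 0.25, Phat,
               tolerance = 6 * mom$se_P[1, 1, k] / Phat)
})

test_that("halving the integration step moves moments by less than a standard error", {
  prob <- make_toy_problem(0.5)
  times <- seq(0, 5, length.out = 26)
  ctrl <- list(U = rbind(rep(0.1, 26), rep(0.9, 26)), times = times)
  e1 <- simulate_trials(prob, ctrl, trials = 2e4, seed = 9, dt = 0.02)
  e2 <- simulate_trials(prob, ctrl, trials = 2e4, seed = 9, dt = 0.01)
  m1 <- empirical_moments(e1); m2 <- empirical_moments(e2)
  k <- 26
  se_diff <- sqrt(m1$se_m[1, k]^2 + m2$se_m[1, k]^2)
  expect_lt(abs(m1$m[1, k] - m2$m[1, k]), se_diff)
})

test_that("copies expansion reproduces the support and its bookkeeping", {
  prob <- make_toy_problem(0.3)
  cp <- s_copies_expand(prob)
  expect_equal(cp$weights, c(0.7, 0.3))
  expect_equal(cp$copies, 2)
  expect_equal(cp$dim, 2)  # n * s
  # deterministic start: augmented state reduces to (m, D), also dimension 2;
  # with initial-state uncertainty the generic (m, P, D) form has dimension 3
  expect_equal(build_augmented(prob)$dim, 2)
  expect_equal(build_augmented(make_toy_problem(0.3, P0 = 0.5))$dim, 3)

  # preconditions
  gauss <- make_toy_problem(0.3)
  gauss$xi$support <- NULL
  expect_error(s_copies_expand(gauss), "support")
  expect_error(s_copies_expand(make_toy_problem(0.3, multiplicative_noise = TRUE)),
               "diffusion")
  expect_error(s_copies_expand(make_toy_problem(0.3, P0 = 0.5)), "deterministic")
})

test_that("copies expansion computes the exact expected cost of an affine system", {
  # fixed control; expected cost from the stacked copies equals the
  # probability-weighted costs of the two deterministic scenarios, and both
  # match the mean/covariance cost of the augmentation (affine exactness)
  prob <- make_toy_problem(0.3)
  cp <- s_copies_expand(prob)
  aug <- build_augmented(prob)
  times <- seq(0, 5, length.out = 41)
  U <- rbind(rep(-0.2, 41), rep(0.7, 41))
  Zc <- propagate_augmented(cp, U, times)
  Za <- propagate_augmented(aug, U, times)
  Jc <- mean_cov_cost(cp, Zc, U, times)
  Ja <- mean_cov_cost(aug, Za, U, times)
  expect_equal(Jc, Ja, tolerance = 1e-6 * Ja)
})

test_that("success rate applies the angular window and overshoot rule", {
  mk_ens <- function(paths) {
    # paths: list of angle trajectories
    K <- length(paths); N <- length(paths[[1]])
    st <- array(0, c(1, N, K))
    for (k in seq_len(K)) st[1, , k] <- paths[[k]]
    structure(list(states = st, xi = matrix(0, 1, K),
                   times = seq(0, 1, length.out = N), dt = 0.01, seed = 1,
                   trials = K, excluded = 0), class = "usooc_ensemble")
  }
  target <- pi / 6
  exact <- mk_ens(list(rep(target, 5), rep(target, 5)))
  expect_equal(as.numeric(success_rate(exact, target, 0.076)), 1)
  expect_equal(as.numeric(success_rate(exact, target, 0)), 1)  # exact hit allowed
  noisy <- mk_ens(list(c(0, 0.2, 0.4, 0.5, target + 0.05),     # ok
                       c(0, 0.2, 0.7, 0.6, target),            # overshoots
                       c(0, 0.1, 0.2, 0.3, target - 0.2)))     # undershoots
  expect_equal(as.numeric(success_rate(noisy, target, 0.076)), 1 / 3)
  expect_equal(as.numeric(success_rate(noisy, target, 0.076,
                                       overshoot_rule = FALSE)), 2 / 3)
})
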