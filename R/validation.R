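# Monte-Carlo validation of the moment predictions, plus the exact
# copies-expansion reformulation for discrete random parameters.

sqrtm_psd <- function(M) {
  eg <- eigen(symm(M), symmetric = TRUE)
  eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
}

#' Simulate trials of the original uncertain stochastic system
#'
#' Euler-Maruyama integration of the uncertain SDE under a fixed open-loop
#' control: each trial draws the random parameter from its discrete support
#' (or from a Gaussian with the specified moments when no support is given —
#' reported with a message, since only the first two moments are specified),
#' draws the initial state from `N(m0, P0)`, and integrates with independent
#' Wiener increments. Trials that blow up (non-finite states) are excluded
#' and counted.
#'
#' @param problem a `usooc_problem` (its `drift` must accept matrix inputs for
#'   vectorized simulation; non-vectorized problems fall back to a per-trial
#'   loop).
#' @param control a `usooc_solution`, a `list(U =, times =)`, or a
#'   `function(t)` returning the control vector.
#' @param trials number of trials (>= 1).
#' @param dt Euler-Maruyama step; defaults to a tenth of the control grid
#'   spacing.
#' @param seed RNG seed (local to the call; the global RNG state is restored).
#' @param record_times times at which trajectories are stored (defaults to
#'   the control grid).
#' @return an object of class `usooc_ensemble`: `states` (n x N x trials
#'   array at `record_times`), `xi` (p x trials draws), counts of excluded
#'   trials, and the configuration.
#' @export
simulate_trials <- function(problem, control, trials, dt = NULL, seed = 1,
                            record_times = NULL) {
  stopifnot(trials >= 1)
  if (!isTRUE(problem$validated)) problem <- validate_problem(problem)
  n <- problem$n; p <- problem$p
  horizon <- problem$horizon

  if (inherits(control, "usooc_solution")) {
    control <- list(U = control$U, times = control$times)
  }
  if (is.function(control)) {
    ctrl_times <- seq(0, horizon, length.out = 101)
    ufun <- control
  } else {
    ctrl_times <- control$times
    ufun <- control_interpolant(control$U, ctrl_times)
  }
  if (is.null(dt)) dt <- min(diff(ctrl_times)) / 10
  if (is.null(record_times)) record_times <- ctrl_times
  # simulation may extend beyond the planning horizon (e.g. a post-movement
  # hold); the control interpolant clamps to its terminal value there
  horizon <- max(horizon, max(record_times))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  # parameter draws
  if (!is.null(problem$xi$support)) {
    probs <- vapply(problem$xi$support, function(s) s$prob, numeric(1))
    vals <- vapply(problem$xi$support, function(s) as.numeric(s$value), numeric(p))
    vals <- matrix(vals, nrow = p)
    idx <- sample.int(length(probs), trials, replace = TRUE, prob = probs)
    Xi <- vals[, idx, drop = FALSE]
  } else {
    message("xi has no discrete support: sampling from a Gaussian with the ",
            "specified mean and covariance")
    Z <- matrix(stats::rnorm(p * trials), p, trials)
    Xi <- problem$xi$mu + sqrtm_psd(problem$xi$sigma) %*% Z
  }

  # initial states
  X <- problem$init$m0 +
    sqrtm_psd(problem$init$p0) %*% matrix(stats::rnorm(n * trials), n, trials)

  nstep <- ceiling(horizon / dt)
  dt <- horizon / nstep
  n_rec <- length(record_times)
  states <- array(NA_real_, c(n, n_rec, trials))
  rec_idx <- 1
  record <- function(X, t) {
    while (rec_idx <= n_rec && record_times[rec_idx] <= t + 1e-12) {
      states[, rec_idx, ] <<- X
      rec_idx <<- rec_idx + 1
    }
  }
  record(X, 0)

  has_diff <- !is.null(problem$diffusion)
  vectorized <- isTRUE(problem$vectorized)
  t <- 0
  for (s in seq_len(nstep)) {
    u <- ufun(t)
    if (vectorized) {
      dX <- problem$drift(X, u, t, Xi) * dt
    } else {
      dX <- vapply(seq_len(trials),
                   function(k) problem$drift(X[, k], u, t, Xi[, k]) * dt,
                   numeric(n))
      dX <- matrix(dX, n, trials)
    }
    if (has_diff) {
      G <- problem$diffusion(X[, 1], u, t)
      d_w <- ncol(G)
      if (problem$diffusion_state_independent) {
        dW <- matrix(stats::rnorm(d_w * trials, sd = sqrt(dt)), d_w, trials)
        dX <- dX + G %*% dW
      } else {
        dW <- matrix(stats::rnorm(d_w * trials, sd = sqrt(dt)), d_w, trials)
        for (k in seq_len(trials)) {
          dX[, k] <- dX[, k] + problem$diffusion(X[, k], u, t) %*% dW[, k]
        }
      }
    }
    X <- X + dX
    t <- t + dt
    record(X, t)
  }

  finite <- apply(is.finite(states), 3, all)
  excluded <- sum(!finite)
  if (excluded > 0) {
    warning(excluded, " trial(s) diverged and were excluded")
    states <- states[, , finite, drop = FALSE]
    Xi <- Xi[, finite, drop = FALSE]
  }
  structure(list(
    states = states, xi = Xi, times = record_times, dt = dt, seed = seed,
    trials = dim(states)[3], excluded = excluded, problem = problem
  ), class = "usooc_ensemble")
}

#' @export
print.usooc_ensemble <- function(x, ...) {
  cat("<usooc_ensemble>", x$trials, "trials,", length(x$times),
      "recorded times, dt =", signif(x$dt, 3), "\n")
  invisible(x)
}

#' Empirical moments of a simulated ensemble
#'
#' Unbiased sample estimators of the state mean, covariance and
#' state-parameter cross-covariance at each recorded time, with standard
#' errors obtained from the sampling variability of the corresponding
#' products.
#'
#' @param ensemble a `usooc_ensemble` with at least 2 trials.
#' @return list with arrays `m` (n x N), `P` (n x n x N), `D` (n x p x N) and
#'   matching standard-error arrays `se_m`, `se_P`, `se_D`.
#' @export
empirical_moments <- function(ensemble) {
  K <- ensemble$trials
  if (K < 2) stop("at least 2 trials are required to estimate moments", call. = FALSE)
  st <- ensemble$states
  n <- dim(st)[1]; N <- dim(st)[2]
  p <- nrow(ensemble$xi)
  xi_c <- ensemble$xi - rowMeans(ensemble$xi)

  m <- matrix(0, n, N); se_m <- matrix(0, n, N)
  P <- array(0, c(n, n, N)); se_P <- array(0, c(n, n, N))
  D <- array(0, c(n, p, N)); se_D <- array(0, c(n, p, N))
  for (k in seq_len(N)) {
    Xk <- matrix(st[, k, ], n, K)
    mk <- rowMeans(Xk)
    Xc <- Xk - mk
    m[, k] <- mk
    se_m[, k] <- sqrt(rowSums(Xc^2) / (K - 1)) / sqrt(K)
    P[, , k] <- tcrossprod(Xc) / (K - 1)
    D[, , k] <- Xc %*% t(xi_c) / (K - 1)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        prod_ij <- Xc[i, ] * Xc[j, ]
        se_P[i, j, k] <- stats::sd(prod_ij) / sqrt(K)
      }
      for (j in seq_len(p)) {
        se_D[i, j, k] <- stats::sd(Xc[i, ] * xi_c[j, ]) / sqrt(K)
      }
    }
  }
  list(m = m, se_m = se_m, P = P, se_P = se_P, D = D, se_D = se_D, trials = K)
}

#' Expand a discrete-parameter problem into stacked copies
#'
#' For a discrete random parameter with `s` support values (and a
#' deterministic initial state, no diffusion), the expected cost is computed
#' exactly by stacking one copy of the dynamics per support value with a
#' single shared control, weighting each copy's cost by its probability.
#' Terminal mean constraints become probability-weighted combinations across
#' copies. The result exposes the same interface as [build_augmented()] and
#' can be transcribed and solved with [solve_usooc()] (pass it as `aug`);
#' it serves as an exact oracle for the moment-augmentation path on affine
#' problems.
#'
#' @param problem a validated `usooc_problem` with discrete support, `P0 = 0`
#'   and no diffusion.
#' @return an object of class `usooc_augmented` (copies layout).
#' @export
s_copies_expand <- function(problem) {
  if (!isTRUE(problem$validated)) problem <- validate_problem(problem)
  if (is.null(problem$xi$support)) {
    stop("xi has no discrete support: use the augmented (m, P, D) path",
         call. = FALSE)
  }
  if (!is.null(problem$diffusion)) {
    stop("copies expansion requires a diffusion-free system", call. = FALSE)
  }
  if (any(problem$init$p0 != 0)) {
    stop("copies expansion requires a deterministic initial state", call. = FALSE)
  }
  n <- problem$n
  s <- length(problem$xi$support)
  wgt <- vapply(problem$xi$support, function(x) x$prob, numeric(1))
  vals <- lapply(problem$xi$support, function(x) as.numeric(x$value))
  dim <- n * s
  idx <- function(j) (j - 1) * n + seq_len(n)
  cost <- problem$cost

  rhs <- function(z, u, t) {
    out <- numeric(dim)
    for (j in seq_len(s)) {
      out[idx(j)] <- problem$drift(z[idx(j)], u, t, vals[[j]])
    }
    out
  }
  running <- function(z, u, t) {
    val <- drop(crossprod(u, cost$R %*% u))
    if (!is.null(cost$Q)) {
      ref <- running_reference(cost, t, n)
      for (j in seq_len(s)) {
        dx <- z[idx(j)] - ref
        val <- val + wgt[j] * drop(crossprod(dx, cost$Q %*% dx))
      }
    }
    val
  }
  terminal <- function(z) {
    val <- 0
    if (!is.null(cost$Qf)) {
      ref <- if (is.null(cost$terminal_reference)) rep(0, n) else cost$terminal_reference
      for (j in seq_len(s)) {
        dx <- z[idx(j)] - ref
        val <- val + wgt[j] * drop(crossprod(dx, cost$Qf %*% dx))
      }
    }
    val
  }
  running_grad <- function(z, u, t) {
    gz <- numeric(dim)
    if (!is.null(cost$Q)) {
      ref <- running_reference(cost, t, n)
      for (j in seq_len(s)) {
        gz[idx(j)] <- wgt[j] * as.numeric(2 * cost$Q %*% (z[idx(j)] - ref))
      }
    }
    list(gz = gz, gu = as.numeric(2 * cost$R %*% u))
  }
  terminal_grad <- function(z) {
    gz <- numeric(dim)
    if (!is.null(cost$Qf)) {
      ref <- if (is.null(cost$terminal_reference)) rep(0, n) else cost$terminal_reference
      for (j in seq_len(s)) {
        gz[idx(j)] <- wgt[j] * as.numeric(2 * cost$Qf %*% (z[idx(j)] - ref))
      }
    }
    gz
  }
  m_ctrl <- problem$m
  H_run <- matrix(0, dim + m_ctrl, dim + m_ctrl)
  if (!is.null(cost$Q)) {
    for (j in seq_len(s)) H_run[idx(j), idx(j)] <- wgt[j] * 2 * cost$Q
  }
  H_run[dim + seq_len(m_ctrl), dim + seq_len(m_ctrl)] <- 2 * cost$R
  H_term <- matrix(0, dim, dim)
  if (!is.null(cost$Qf)) {
    for (j in seq_len(s)) H_term[idx(j), idx(j)] <- wgt[j] * 2 * cost$Qf
  }

  terminal_constraint <- NULL
  if (!is.null(problem$terminal_mean)) {
    tm <- problem$terminal_mean
    Tmat <- matrix(0, length(tm$idx), dim)
    for (j in seq_len(s)) {
      Tmat[cbind(seq_along(tm$idx), (j - 1) * n + tm$idx)] <- wgt[j]
    }
    terminal_constraint <- list(
      fun = function(zT) as.numeric(Tmat %*% zT) - tm$value,
      jac = function(zT) Tmat
    )
  }

  structure(list(
    problem = problem, dim = dim, variant = "copies", split = FALSE,
    factorized = FALSE, reduced = FALSE, copies = s, weights = wgt,
    rhs = rhs, z0 = rep(problem$init$m0, s),
    unpack = function(z) {
      xs <- matrix(z, n, s)
      mm <- as.numeric(xs %*% wgt)
      dev <- xs - mm
      list(m = mm, P = dev %*% (wgt * t(dev)), D = NULL, L = NULL,
           P1 = NULL, P2 = NULL, copies = xs)
    },
    layout = list(idx_m = seq_len(n), idx_L = integer(0), idx_P2 = integer(0),
                  idx_D = integer(0), has_L = FALSE, has_P2 = FALSE,
                  has_D = FALSE),
    z_lower = rep(-Inf, dim), z_upper = rep(Inf, dim), l_floor = 0,
    running = running, terminal = terminal,
    running_grad = running_grad, terminal_grad = terminal_grad,
    running_hess = function(z, u, t) H_run,
    terminal_hess = function(z) H_term,
    hess_const = TRUE,
    terminal_constraint = terminal_constraint
  ), class = "usooc_augmented")
}

#' Task success rate of a simulated ensemble
#'
#' Fraction of trials whose final angle (state component `component`) lies
#' within `halfwidth` of `target` and which never overshoot beyond the far
#' edge of that window. The window is fully configurable and recorded in the
#' result's attributes.
#'
#' @param ensemble a `usooc_ensemble`.
#' @param target target angle (rad).
#' @param halfwidth half-width of the acceptance window (rad).
#' @param component state component holding the angle.
#' @param overshoot_rule if `TRUE` (default) a trial fails when the angle
#'   ever exceeds `target + halfwidth`.
#' @return the success fraction in `[0, 1]`, with attributes recording the
#'   criterion.
#' @export
success_rate <- function(ensemble, target, halfwidth, component = 1,
                         overshoot_rule = TRUE) {
  if (!inherits(ensemble, "usooc_ensemble") || ensemble$trials < 1) {
    stop("a non-empty usooc_ensemble is required", call. = FALSE)
  }
  theta <- ensemble$states[component, , , drop = FALSE]
  N <- dim(theta)[2]
  final_ok <- abs(theta[1, N, ] - target) <= halfwidth
  ok <- final_ok
  if (overshoot_rule) {
    max_theta <- apply(theta[1, , , drop = FALSE], 3, max)
    ok <- ok & (max_theta <= target + halfwidth)
  }
  out <- mean(ok)
  attr(out, "criterion") <- list(target = target, halfwidth = halfwidth,
                                 component = component,
                                 overshoot_rule = overshoot_rule)
  out
}
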