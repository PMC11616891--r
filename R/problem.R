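#' Moments of a random environmental parameter
#'
#' Specifies the p-dimensional random parameter entering the drift of an
#' uncertain control system through its mean and covariance, optionally with a
#' discrete support. The optimal open-loop solution depends on the parameter
#' distribution only through its first two moments; the support is needed only
#' for exact sampling and for the copies-expansion oracle.
#'
#' @param mu numeric vector, mean of the parameter.
#' @param sigma covariance matrix (a scalar is promoted to a 1x1 matrix);
#'   must be symmetric positive semidefinite.
#' @param support optional list of `list(value =, prob =)` pairs describing a
#'   discrete distribution. Probabilities must sum to 1 and the implied
#'   moments must match `mu` and `sigma`.
#' @return an object of class `usooc_random_parameter`.
#' @seealso [bernoulli_moments()]
#' @export
random_parameter <- function(mu, sigma, support = NULL) {
  mu <- as.numeric(mu)
  p <- length(mu)
  sigma <- as.matrix(sigma)
  if (!all(dim(sigma) == c(p, p))) {
    stop("sigma: must be a ", p, "x", p, " matrix to match mu", call. = FALSE)
  }
  if (!is_psd(sigma)) {
    stop("sigma: must be symmetric positive semidefinite", call. = FALSE)
  }
  if (!is.null(support)) {
    probs <- vapply(support, function(s) s$prob, numeric(1))
    if (abs(sum(probs) - 1) > 1e-10) {
      stop("support: probabilities must sum to 1", call. = FALSE)
    }
    vals <- vapply(support, function(s) as.numeric(s$value), numeric(p))
    vals <- matrix(vals, nrow = p)
    mu_s <- drop(vals %*% probs)
    dev <- vals - mu_s
    sig_s <- dev %*% (probs * t(dev))
    if (max(abs(mu_s - mu)) > 1e-8 || max(abs(sig_s - sigma)) > 1e-8) {
      stop("support: moments of the discrete support do not match (mu, sigma)",
           call. = FALSE)
    }
  }
  structure(list(mu = mu, sigma = sigma, support = support, p = p),
            class = "usooc_random_parameter")
}

#' Bernoulli disturbance moments
#'
#' A scalar disturbance present with probability `alpha` and absent otherwise:
#' mean `alpha`, variance `alpha * (1 - alpha)`. The variance is the task
#' uncertainty measure used throughout the probability sweeps.
#'
#' @param alpha probability of the disturbance, in `[0, 1]`.
#' @return a `usooc_random_parameter` with `p = 1` and the two-point support.
#' @examples
#' bernoulli_moments(0.5)$sigma  # 0.25
#' @export
bernoulli_moments <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("alpha: must be a probability in [0, 1]", call. = FALSE)
  }
  random_parameter(
    mu = alpha,
    sigma = alpha * (1 - alpha),
    support = list(list(value = 0, prob = 1 - alpha),
                   list(value = 1, prob = alpha))
  )
}

#' Initial-state distribution
#'
#' @param m0 mean of the initial state (numeric vector, length n).
#' @param p0 initial covariance; a scalar is promoted to `p0 * I`. Must be
#'   symmetric positive semidefinite.
#' @return an object of class `usooc_initial_state`.
#' @export
initial_state <- function(m0, p0 = 0) {
  m0 <- as.numeric(m0)
  n <- length(m0)
  if (length(p0) == 1) p0 <- diag(as.numeric(p0), n)
  p0 <- as.matrix(p0)
  if (!all(dim(p0) == c(n, n))) {
    stop("p0: must be an ", n, "x", n, " matrix to match m0", call. = FALSE)
  }
  if (!is_psd(p0)) stop("p0: must be symmetric positive semidefinite", call. = FALSE)
  structure(list(m0 = m0, p0 = p0, n = n), class = "usooc_initial_state")
}

#' Quadratic expected cost in mean/covariance form
#'
#' Encodes the expected cost
#' `E[x(T)' Qf x(T) + int u'Ru + x'Qx dt]`, which rewrites over the mean `m`
#' and covariance `P` as
#' `m(T)'Qf m(T) + tr(Qf P(T)) + int (u'Ru + m'Qm + tr(QP)) dt`.
#' References shift the quadratic state terms to deviations from a target.
#' Non-quadratic mean/covariance functionals (e.g. a terminal endpoint-variance
#' term through a kinematic Jacobian) are supplied through `extra_terminal` /
#' `extra_running`.
#'
#' @param R control weight matrix (positive definite).
#' @param Q running state weight (positive semidefinite); default zero.
#' @param Qf terminal state weight (positive semidefinite); default zero.
#' @param state_reference optional running reference: a constant n-vector or a
#'   function of time returning one.
#' @param terminal_reference optional n-vector reference for the terminal term.
#' @param extra_terminal optional `function(m, P)` added to the terminal cost.
#' @param extra_running optional `function(m, P, u, t)` added to the running
#'   cost density.
#' @return an object of class `usooc_cost`.
#' @export
quadratic_cost <- function(R, Q = NULL, Qf = NULL, state_reference = NULL,
                           terminal_reference = NULL, extra_terminal = NULL,
                           extra_running = NULL) {
  R <- as.matrix(R)
  ev <- eigen(symm(R), symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("R: must be positive definite", call. = FALSE)
  if (!is.null(Q)) {
    Q <- as.matrix(Q)
    if (!is_psd(Q)) stop("Q: must be positive semidefinite", call. = FALSE)
  }
  if (!is.null(Qf)) {
    Qf <- as.matrix(Qf)
    if (!is_psd(Qf)) stop("Qf: must be positive semidefinite", call. = FALSE)
  }
  structure(list(R = R, Q = Q, Qf = Qf,
                 state_reference = state_reference,
                 terminal_reference = terminal_reference,
                 extra_terminal = extra_terminal,
                 extra_running = extra_running),
            class = "usooc_cost")
}

#' Define an uncertain stochastic optimal open-loop control problem
#'
#' The system is the Ito stochastic differential equation
#' `dx = f(x, u(t), t; xi) dt + G(x, u(t), t) dw` with a random parameter
#' `xi` (mean/covariance given by `xi`), a random initial state, and a
#' deterministic open-loop control `u(t)` on `[0, horizon]` minimizing an
#' expected cost over `(xi, x0, w)`.
#'
#' @param drift `function(x, u, t, xi)` returning the state derivative
#'   (length n). If `vectorized = TRUE` it must also accept an `n x K` state
#'   matrix together with a `p x K` parameter matrix and return `n x K`
#'   (used by the Monte-Carlo simulator).
#' @param diffusion `NULL` for a noise-free system, else
#'   `function(x, u, t)` returning the `n x d` diffusion matrix.
#' @param xi a [random_parameter()] (or [bernoulli_moments()]) object.
#' @param init an [initial_state()] object.
#' @param horizon planning horizon T in seconds.
#' @param cost a [quadratic_cost()] object.
#' @param n,m state and control dimensions (`p` is taken from `xi`).
#' @param jac_x,jac_xi optional analytic Jacobians `function(x, u, t, xi)`
#'   returning the `n x n` and `n x p` drift Jacobians; central finite
#'   differences are used when absent.
#' @param terminal_mean optional equality constraint on the terminal mean:
#'   `list(idx =, value =)` constrains `m(T)[idx] == value`.
#' @param control_bounds `list(lower =, upper =)` per-channel bounds
#'   (use `-Inf`/`Inf` for free channels).
#' @param affine_in_state declare the drift affine in `x` at fixed `(u, t)`
#'   (checked numerically by [validate_problem()]).
#' @param diffusion_state_independent declare `G` independent of `x`.
#' @param vectorized whether `drift` supports matrix inputs across trials.
#' @param metrics optional list of model-specific summaries (e.g. a
#'   `stiffness` function over a control/state record) consumed by
#'   [mean_stiffness()].
#' @param name model label used in printing and exports.
#' @return an object of class `usooc_problem` (not yet validated; see
#'   [validate_problem()]).
#' @export
uncertain_control_problem <- function(drift, diffusion = NULL, xi, init,
                                      horizon, cost, n, m,
                                      jac_x = NULL, jac_xi = NULL,
                                      terminal_mean = NULL,
                                      control_bounds = NULL,
                                      affine_in_state = FALSE,
                                      diffusion_state_independent = TRUE,
                                      vectorized = FALSE,
                                      metrics = NULL,
                                      name = "problem") {
  stopifnot(inherits(xi, "usooc_random_parameter"),
            inherits(init, "usooc_initial_state"),
            inherits(cost, "usooc_cost"))
  if (init$n != n) stop("init: m0 has length ", init$n, " but n = ", n, call. = FALSE)
  if (horizon <= 0) stop("horizon: must be positive", call. = FALSE)
  if (is.null(control_bounds)) {
    control_bounds <- list(lower = rep(-Inf, m), upper = rep(Inf, m))
  }
  control_bounds$lower <- rep_len(control_bounds$lower, m)
  control_bounds$upper <- rep_len(control_bounds$upper, m)
  structure(list(
    drift = drift, diffusion = diffusion, xi = xi, init = init,
    horizon = horizon, cost = cost, n = n, m = m, p = xi$p,
    jac_x = jac_x, jac_xi = jac_xi,
    terminal_mean = terminal_mean, control_bounds = control_bounds,
    affine_in_state = affine_in_state,
    diffusion_state_independent = diffusion_state_independent,
    vectorized = vectorized, metrics = metrics, name = name,
    variant = NULL, validated = FALSE
  ), class = "usooc_problem")
}

#' @export
print.usooc_problem <- function(x, ...) {
  cat("<usooc_problem>", x$name, "\n")
  cat("  state n =", x$n, "| control m =", x$m, "| parameter p =", x$p, "\n")
  cat("  horizon T =", x$horizon, "s | diffusion:",
      if (is.null(x$diffusion)) "none" else "present", "\n")
  if (!is.null(x$variant)) cat("  variant:", x$variant, "\n")
  invisible(x)
}

#' Dimension of the augmented deterministic state
#'
#' Counts the mean (n), the packed symmetric covariance (n(n+1)/2) and the
#' cross-covariance (np): `n * (p + 1 + (n + 1) / 2)`. With a perfectly known
#' initial state the covariance can be reconstructed from the cross-covariance
#' and the count reduces to `n * (p + 1)`. The augmented dimension therefore
#' grows quadratically in the state dimension but only linearly in the
#' parameter dimension.
#'
#' @param n state dimension (>= 1).
#' @param p random-parameter dimension (>= 0).
#' @param deterministic_init `TRUE` when the initial state is known exactly.
#' @return integer dimension.
#' @examples
#' augmented_dimension(4, 1)  # 18
#' @export
augmented_dimension <- function(n, p, deterministic_init = FALSE) {
  stopifnot(n >= 1, p >= 0)
  if (deterministic_init) n * (p + 1) else as.integer(n * (p + 1) + n * (n + 1) / 2)
}

#' Linearize the drift about the mean
#'
#' Returns the Jacobians `A = df/dx` and `C = df/dxi` evaluated at
#' `(m, u, t, mu)` together with the diffusion matrix at the same point. These
#' are the coefficients of the covariance and cross-covariance propagation in
#' the statistically linearized moment dynamics.
#'
#' @param problem a `usooc_problem`.
#' @param m state (mean) vector.
#' @param u control vector.
#' @param t time.
#' @return list with elements `A` (n x n), `C` (n x p) and `G` (n x d or NULL).
#' @export
linearize <- function(problem, m, u, t) {
  mu <- problem$xi$mu
  f0 <- problem$drift(m, u, t, mu)
  if (any(!is.finite(f0))) {
    stop("drift evaluation is not finite at (m, u, t) = (",
         paste(signif(m, 4), collapse = ","), "; ",
         paste(signif(u, 4), collapse = ","), "; ", signif(t, 4), ")",
         call. = FALSE)
  }
  A <- if (!is.null(problem$jac_x)) {
    problem$jac_x(m, u, t, mu)
  } else {
    fd_jacobian(function(x) problem$drift(x, u, t, mu), m)
  }
  C <- if (!is.null(problem$jac_xi)) {
    problem$jac_xi(m, u, t, mu)
  } else {
    fd_jacobian(function(xi) problem$drift(m, u, t, xi), mu)
  }
  G <- if (is.null(problem$diffusion)) NULL else problem$diffusion(m, u, t)
  list(A = matrix(A, problem$n, problem$n),
       C = matrix(C, problem$n, problem$p),
       G = G)
}

# Central finite-difference Jacobian with step 1e-6 * (1 + |value|).
fd_jacobian <- function(fun, x0) {
  k <- length(x0)
  f0 <- fun(x0)
  J <- matrix(0, length(f0), k)
  for (j in seq_len(k)) {
    h <- 1e-6 * (1 + abs(x0[j]))
    xp <- x0; xp[j] <- xp[j] + h
    xm <- x0; xm[j] <- xm[j] - h
    J[, j] <- (fun(xp) - fun(xm)) / (2 * h)
  }
  J
}

#' Validate a problem and annotate its structural variant
#'
#' Checks moment matrices, dimension consistency and the declared structure
#' flags (affinity of the drift in the state, affinity in the parameter,
#' state-independence of the diffusion) by numerical probing, then annotates
#' the problem with the applicable deterministic reformulation:
#' `affine_no_diff`, `nonlinear_no_diff`, `affine_diff` or `general`.
#'
#' @param problem a `usooc_problem`.
#' @param n_probes number of probe points for the structural checks.
#' @return the problem with `variant` set and `validated = TRUE`.
#' @export
validate_problem <- function(problem, n_probes = 10) {
  stopifnot(inherits(problem, "usooc_problem"))
  n <- problem$n; m <- problem$m; p <- problem$p
  if (!is_psd(problem$xi$sigma)) {
    stop("sigma: must be symmetric positive semidefinite", call. = FALSE)
  }
  if (!is_psd(problem$init$p0)) {
    stop("p0: must be symmetric positive semidefinite", call. = FALSE)
  }

  # probe states/controls around the initial mean and admissible controls
  probes <- probe_points(n + m + 1, n_probes)
  lo <- pmax(problem$control_bounds$lower, -1)
  hi <- pmin(problem$control_bounds$upper, 1)
  mid <- (lo + hi) / 2
  half <- (hi - lo) / 2
  mu <- problem$xi$mu

  d0 <- problem$drift(problem$init$m0, mid, 0, mu)
  if (length(d0) != n) {
    stop("drift: returns length ", length(d0), " but n = ", n, call. = FALSE)
  }

  affine_ok <- TRUE
  diff_state_free <- TRUE
  for (i in seq_len(n_probes)) {
    x1 <- problem$init$m0 + 0.5 * probes[i, 1:n]
    x2 <- problem$init$m0 - 0.3 * probes[i, 1:n]
    u <- mid + half * probes[i, n + seq_len(m)]
    t <- problem$horizon * (probes[i, n + m + 1] + 1) / 2
    f1 <- problem$drift(x1, u, t, mu)
    f2 <- problem$drift(x2, u, t, mu)
    fmid <- problem$drift((x1 + x2) / 2, u, t, mu)
    if (any(!is.finite(c(f1, f2, fmid)))) {
      stop("drift: non-finite value at a probe point (state ",
           paste(signif(x1, 3), collapse = ","), ")", call. = FALSE)
    }
    scale <- max(1, abs(f1), abs(f2))
    if (max(abs((f1 + f2) / 2 - fmid)) > 1e-6 * scale) affine_ok <- FALSE
    if (!is.null(problem$diffusion)) {
      G1 <- problem$diffusion(x1, u, t)
      G2 <- problem$diffusion(x2, u, t)
      if (max(abs(G1 - G2)) > 1e-10 * max(1, max(abs(G1)))) diff_state_free <- FALSE
    }
  }
  if (problem$affine_in_state && !affine_ok) {
    stop("affine_in_state: drift fails the affinity probe; ",
         "declare the problem nonlinear", call. = FALSE)
  }
  if (problem$diffusion_state_independent && !diff_state_free) {
    stop("diffusion_state_independent: diffusion varies with the state at ",
         "probe points", call. = FALSE)
  }

  has_diffusion <- !is.null(problem$diffusion)
  if (has_diffusion) {
    # treat an identically zero diffusion as absent
    Gs <- problem$diffusion(problem$init$m0, mid, problem$horizon / 2)
    if (all(abs(Gs) == 0) && affine_ok) has_diffusion <- has_diffusion # keep as-is
  }
  problem$variant <- if (!has_diffusion) {
    if (problem$affine_in_state && affine_ok) "affine_no_diff" else "nonlinear_no_diff"
  } else {
    if (problem$affine_in_state && affine_ok &&
        problem$diffusion_state_independent) "affine_diff" else "general"
  }
  problem$validated <- TRUE
  problem
}
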