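#' Build the deterministic augmented-state ODE of a problem
#'
#' Replaces the uncertain stochastic system by a deterministic ODE over the
#' state mean `m`, a covariance block and the state-parameter cross-covariance
#' `D`, according to the structural variant annotated by [validate_problem()]:
#'
#' The covariance is carried in the split form `P = P1 + D Sigma^-1 D'`:
#' the noise/initial-state part obeys `P1' = A P1 + P1 A' + G G'`
#' (`P1(0) = P0`, with `G = 0` for the diffusion-free variants) and the
#' parameter-induced part is determined exactly by the cross-covariance,
#' since `D Sigma^-1 D'` satisfies the parameter-covariance equation
#' `P2' = A P2 + P2 A' + C D' + D C'` with `P2(0) = 0` for any `A(t)`,
#' `C(t)`. Carrying the (rank-deficient, rank <= p) parameter part through
#' `D` instead of its own matrix block keeps it positive semidefinite by
#' construction and keeps the factor dynamics of `P1` free of
#' cross-covariance couplings. `D' = A D + C Sigma` with `D(0) = 0`. For
#' affine drifts the moments are exact; for nonlinear drifts the mean
#' propagates through the full drift and only the covariance uses the
#' Jacobians `A`, `C` at the mean (statistical linearization).
#'
#' With `factorized = TRUE` the `P`-or-`P1` block is propagated through its
#' lower-triangular factor `L` (`P = L L'`), so that positive definiteness
#' along solver iterates reduces to box constraints on the factor diagonal.
#' A singular initial covariance is floored to `P0 + p0_floor * I` before
#' factorization.
#'
#' @param problem a validated `usooc_problem` ([validate_problem()] is called
#'   if needed).
#' @param factorized propagate the covariance factor instead of the covariance
#'   (default): the factor's floored diagonal keeps the covariance positive
#'   definite along arbitrary solver iterates through box constraints alone.
#'   `factorized = FALSE` propagates the packed covariance directly and is
#'   intended for trajectory analysis (e.g. two-path comparisons), not for
#'   optimization.
#' @param reduced use the reduced `(m, D)` state with
#'   `P = D Sigma^-1 D'`; only valid for an affine drift with no diffusion,
#'   a deterministic initial state and invertible `Sigma`.
#' @param p0_floor diagonal floor applied to a singular `P0` before
#'   factorization (ignored when `factorized = FALSE`).
#' @param l_floor lower bound imposed on the factor diagonal by the solver.
#' @return an object of class `usooc_augmented` with fields `dim`, `variant`,
#'   `rhs(z, u, t)`, `z0`, `unpack(z)`, cost callbacks and index layout.
#' @export
build_augmented <- function(problem, factorized = NULL, reduced = FALSE,
                            p0_floor = NULL, l_floor = 1e-6) {
  if (!isTRUE(problem$validated)) problem <- validate_problem(problem)
  n <- problem$n; p <- problem$p
  variant <- problem$variant
  split <- variant %in% c("affine_diff", "general")
  if (is.null(factorized)) factorized <- TRUE
  # scalar degenerate case (deterministic nonzero disturbance with
  # signal-dependent noise): compensating the mean drives the noise magnitude
  # through zero along the optimal path, where the factor dynamics
  # g^2 / (2 L) are knife-edged; there the box constraint P1 >= 0 is the
  # exact semidefiniteness constraint and the covariance is propagated
  # directly
  if (n == 1 && split && all(problem$xi$sigma == 0) &&
      any(problem$xi$mu != 0)) {
    factorized <- FALSE
  }
  # with a diffusion term the noise inflates the covariance away from zero on
  # the first grid interval anyway, and a larger floor keeps the factor
  # dynamics well-conditioned near t = 0
  if (is.null(p0_floor)) p0_floor <- if (split) 1e-5 else 1e-8
  Sigma <- problem$xi$sigma
  mu <- problem$xi$mu
  nL <- n * (n + 1) / 2

  # fast Jacobian closures for the hot rhs path (analytic when supplied)
  jacA <- if (!is.null(problem$jac_x)) {
    function(m, u, t) problem$jac_x(m, u, t, mu)
  } else {
    function(m, u, t) fd_jacobian(function(x) problem$drift(x, u, t, mu), m)
  }
  jacC <- if (!is.null(problem$jac_xi)) {
    function(m, u, t) problem$jac_xi(m, u, t, mu)
  } else {
    function(m, u, t) fd_jacobian(function(xi) problem$drift(m, u, t, xi), mu)
  }
  diffG <- problem$diffusion

  if (reduced) {
    if (variant != "affine_no_diff") {
      stop("reduced augmentation requires an affine drift with no diffusion ",
           "(variant is '", variant, "')", call. = FALSE)
    }
    if (any(problem$init$p0 != 0)) {
      stop("reduced augmentation requires a deterministic initial state (P0 = 0)",
           call. = FALSE)
    }
    if (rcond_psd(Sigma) < 1e-12) {
      stop("Sigma is singular: use the full (m, P, D) propagation instead of ",
           "the reduced form", call. = FALSE)
    }
    idx_m <- seq_len(n)
    idx_D <- n + seq_len(n * p)
    dim <- n * (p + 1)
    Sigma_inv <- solve(Sigma)
    unpack <- function(z) {
      D <- matrix(z[idx_D], n, p)
      P <- D %*% Sigma_inv %*% t(D)
      list(m = z[idx_m], P = P, D = D, L = NULL, P1 = NULL, P2 = NULL)
    }
    rhs <- function(z, u, t) {
      m <- z[idx_m]
      D <- matrix(z[idx_D], n, p)
      A <- jacA(m, u, t)
      C <- jacC(m, u, t)
      c(problem$drift(m, u, t, mu), A %*% D + C %*% Sigma)
    }
    z0 <- c(problem$init$m0, rep(0, n * p))
    Sigma_pinv <- Sigma_inv
    layout <- list(idx_m = idx_m, idx_L = integer(0), idx_P2 = integer(0),
                   idx_D = idx_D, has_L = FALSE, has_P2 = FALSE, has_D = TRUE)
  } else {
    # block structure with exact degenerate reductions: when Sigma = 0 the
    # cross-covariance D and the parameter-induced covariance vanish
    # identically and their blocks are dropped; when additionally P0 = 0 and
    # there is no diffusion, the whole covariance block is dropped and only
    # the mean is propagated
    P0 <- problem$init$p0
    sig_zero <- all(Sigma == 0)
    p0_zero <- all(P0 == 0)
    has_D <- !sig_zero
    has_L <- split || !p0_zero
    Sigma_pinv <- if (has_D) pinv_psd(Sigma) else NULL

    idx_m <- seq_len(n)
    off <- n
    idx_L <- if (has_L) off + seq_len(nL) else integer(0)
    off <- off + length(idx_L)
    idx_D <- if (has_D) off + seq_len(n * p) else integer(0)
    dim <- off + length(idx_D)
    layout <- list(idx_m = idx_m, idx_L = idx_L, idx_P2 = integer(0),
                   idx_D = idx_D, has_L = has_L, has_P2 = FALSE,
                   has_D = has_D)

    zeron <- matrix(0, n, n)
    unpack <- function(z) {
      L <- NULL
      P1 <- zeron
      if (has_L) {
        if (factorized) {
          L <- ltri_unpack(z[idx_L], n)
          P1 <- tcrossprod(L)
        } else {
          P1 <- ltri_unpack(z[idx_L], n, symmetric = TRUE)
        }
      }
      P2 <- NULL
      D <- matrix(0, n, p)
      P <- P1
      if (has_D) {
        D <- matrix(z[idx_D], n, p)
        P2 <- D %*% Sigma_pinv %*% t(D)
        P <- P1 + P2
      }
      list(m = z[idx_m], P = P, D = D, L = L,
           P1 = if (has_L) P1 else NULL, P2 = P2)
    }

    rhs <- function(z, u, t) {
      m <- z[idx_m]
      A <- matrix(jacA(m, u, t), n, n)
      out <- problem$drift(m, u, t, mu)
      if (has_L) {
        # the factored block carries only the noise/initial-state covariance
        # P1' = A P1 + P1 A' + G G'; the parameter-induced part travels with D
        GGt <- if (split) tcrossprod(diffG(m, u, t)) else NULL
        if (factorized) {
          L <- ltri_unpack(z[idx_L], n)
          P1 <- tcrossprod(L)
          AP <- A %*% P1
          S <- AP + t(AP)
          if (split) S <- S + GGt
          M <- forwardsolve(L, t(forwardsolve(L, S)))
          out <- c(out, ltri_pack(L %*% phi_lower(M)))
        } else {
          P1 <- ltri_unpack(z[idx_L], n, symmetric = TRUE)
          AP <- A %*% P1
          S <- AP + t(AP)
          if (split) S <- S + GGt
          out <- c(out, ltri_pack(S))
        }
      }
      if (has_D) {
        D <- matrix(z[idx_D], n, p)
        C <- matrix(jacC(m, u, t), n, p)
        out <- c(out, A %*% D + C %*% Sigma)
      }
      out
    }

    # scalar fast path (n = p = 1): the generic matrix algebra dominates the
    # rhs cost for the bilinear stabilization model
    if (n == 1 && p == 1 && has_D) {
      Sig <- Sigma[1]
      drift1 <- problem$drift
      rhs <- if (has_L && factorized && split) {
        function(z, u, t) {
          A <- jacA(z[1], u, t)[1]
          C <- jacC(z[1], u, t)[1]
          g <- diffG(z[1], u, t)[1]
          c(drift1(z[1], u, t, mu), A * z[2] + g * g / (2 * z[2]),
            A * z[3] + C * Sig)
        }
      } else if (has_L && factorized) {
        function(z, u, t) {
          A <- jacA(z[1], u, t)[1]
          C <- jacC(z[1], u, t)[1]
          c(drift1(z[1], u, t, mu), A * z[2], A * z[3] + C * Sig)
        }
      } else if (has_L && split) {
        function(z, u, t) {
          A <- jacA(z[1], u, t)[1]
          C <- jacC(z[1], u, t)[1]
          g <- diffG(z[1], u, t)[1]
          c(drift1(z[1], u, t, mu), 2 * A * z[2] + g * g,
            A * z[3] + C * Sig)
        }
      } else if (has_L) {
        function(z, u, t) {
          A <- jacA(z[1], u, t)[1]
          C <- jacC(z[1], u, t)[1]
          c(drift1(z[1], u, t, mu), 2 * A * z[2], A * z[3] + C * Sig)
        }
      } else {
        function(z, u, t) {
          A <- jacA(z[1], u, t)[1]
          C <- jacC(z[1], u, t)[1]
          c(drift1(z[1], u, t, mu), A * z[2] + C * Sig)
        }
      }
    }

    z0 <- problem$init$m0
    if (has_L) {
      if (factorized) {
        need_floor <- rcond_psd(P0) < 1e-12
        L0 <- chol_lower(P0, floor = if (need_floor) p0_floor else 0)
        z0 <- c(z0, ltri_pack(L0))
      } else {
        z0 <- c(z0, ltri_pack(P0))
      }
    }
    if (has_D) z0 <- c(z0, rep(0, n * p))
  }

  # box bounds on the augmented coordinates: factor diagonal floored, the
  # diagonal of the unfactorized parameter-induced covariance kept nonnegative
  z_lower <- rep(-Inf, dim)
  z_upper <- rep(Inf, dim)
  if (!reduced) {
    diag_pos <- cumsum(c(1, rev(seq_len(n - 1) + 1)))[seq_len(n)] # packed diag slots
    if (length(idx_L)) {
      # factor diagonals are floored; the unfactorized scalar covariance gets
      # its exact bound P1 >= 0; unfactorized matrix covariances are left
      # unbounded (intended for contraction-stable models where feasibility
      # itself keeps them positive semidefinite)
      z_lower[idx_L[diag_pos]] <- if (factorized) l_floor else if (n == 1) 0 else -Inf
    }
  }

  cost <- problem$cost
  running <- function(z, u, t) {
    s <- unpack(z)
    val <- drop(crossprod(u, cost$R %*% u))
    if (!is.null(cost$Q)) {
      ref <- running_reference(cost, t, n)
      dm <- s$m - ref
      val <- val + drop(crossprod(dm, cost$Q %*% dm)) + sum(cost$Q * s$P)
    }
    if (!is.null(cost$extra_running)) {
      val <- val + cost$extra_running(s$m, s$P, u, t)
    }
    val
  }
  terminal <- function(z) {
    s <- unpack(z)
    val <- 0
    if (!is.null(cost$Qf)) {
      ref <- if (is.null(cost$terminal_reference)) rep(0, n) else cost$terminal_reference
      dm <- s$m - ref
      val <- drop(crossprod(dm, cost$Qf %*% dm)) + sum(cost$Qf * s$P)
    }
    if (!is.null(cost$extra_terminal)) {
      val <- val + cost$extra_terminal(s$m, s$P)
    }
    val
  }

  # ---- analytic cost derivatives over the augmented coordinates -------------
  # trace terms: tr(Q L L') has gradient 2 Q L (packed lower triangle) and a
  # constant PSD Hessian; packed-symmetric blocks enter tr(Q P) linearly.
  pidx <- which(lower.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  sym_weights <- function(W) {
    ww <- 2 * W
    diag(ww) <- diag(W)
    ltri_pack(ww)
  }
  hess_LL <- function(W) {
    np <- nrow(pidx)
    H <- matrix(0, np, np)
    for (s1 in seq_len(np)) {
      for (s2 in seq_len(np)) {
        if (pidx[s1, 2] == pidx[s2, 2]) H[s1, s2] <- 2 * W[pidx[s1, 1], pidx[s2, 1]]
      }
    }
    H
  }
  Q <- cost$Q; Qf <- cost$Qf
  m_idx <- layout$idx_m
  has_extra <- !is.null(cost$extra_running) || !is.null(cost$extra_terminal)

  cov_grad <- function(z, W) {
    # gradient of tr(W P(z)) over the augmented coordinates
    gz <- numeric(dim)

    if (isTRUE(layout$has_L)) {
      if (factorized) {
        L <- ltri_unpack(z[layout$idx_L], n)
        gz[layout$idx_L] <- ltri_pack(2 * W %*% L)
      } else {
        gz[layout$idx_L] <- sym_weights(W)
      }
    }
    if (isTRUE(layout$has_D)) {
      D <- matrix(z[layout$idx_D], n, p)
      gz[layout$idx_D] <- as.numeric(2 * W %*% D %*% Sigma_pinv)
    }
    gz
  }
  Sigma_inv0 <- if (reduced) solve(Sigma) else NULL

  fd_grad_extra <- function(fun, z, u) {
    k <- length(z) + length(u)
    g <- numeric(k)
    x0 <- c(z, u)
    for (j in seq_len(k)) {
      s <- 1e-6 * (1 + abs(x0[j]))
      xp <- x0; xp[j] <- xp[j] + s
      xm <- x0; xm[j] <- xm[j] - s
      g[j] <- (fun(xp) - fun(xm)) / (2 * s)
    }
    g
  }

  running_grad <- function(z, u, t) {
    gz <- numeric(dim)
    gu <- as.numeric(2 * cost$R %*% u)
    if (!is.null(Q)) {
      dm <- z[m_idx] - running_reference(cost, t, n)
      gz[m_idx] <- gz[m_idx] + as.numeric(2 * Q %*% dm)
      gz <- gz + cov_grad(z, Q)
    }
    if (!is.null(cost$extra_running)) {
      fn <- function(x) {
        s <- unpack(x[seq_len(dim)])
        cost$extra_running(s$m, s$P, x[dim + seq_along(u)], t)
      }
      ge <- fd_grad_extra(fn, z, u)
      gz <- gz + ge[seq_len(dim)]
      gu <- gu + ge[dim + seq_along(u)]
    }
    list(gz = gz, gu = gu)
  }

  terminal_grad <- function(z) {
    gz <- numeric(dim)
    if (!is.null(Qf)) {
      ref <- if (is.null(cost$terminal_reference)) rep(0, n) else cost$terminal_reference
      gz[m_idx] <- as.numeric(2 * Qf %*% (z[m_idx] - ref))
      gz <- gz + cov_grad(z, Qf)
    }
    if (!is.null(cost$extra_terminal)) {
      fn <- function(x) {
        s <- unpack(x[seq_len(dim)])
        cost$extra_terminal(s$m, s$P)
      }
      gz <- gz + fd_grad_extra(fn, z, numeric(0))[seq_len(dim)]
    }
    gz
  }

  hess_quad <- function(W) {
    # constant Hessian block of u'Ru + dm'W dm + tr(W P) over (z, u)
    H <- matrix(0, dim + nrow(cost$R), dim + nrow(cost$R))
    if (!is.null(W)) {
      H[m_idx, m_idx] <- 2 * W
      if (!reduced && factorized && isTRUE(layout$has_L)) {
        H[layout$idx_L, layout$idx_L] <- hess_LL(W)
      }
      if (!reduced && isTRUE(layout$has_D)) {
        H[layout$idx_D, layout$idx_D] <- 2 * kronecker(Sigma_pinv, W)
      }
      if (reduced) {
        H[layout$idx_D, layout$idx_D] <- 2 * kronecker(Sigma_inv0, W)
      }
    }
    H
  }
  H_run_const <- {
    H <- hess_quad(Q)
    H[dim + seq_len(nrow(cost$R)), dim + seq_len(nrow(cost$R))] <- 2 * cost$R
    H
  }
  H_term_const <- hess_quad(Qf)[seq_len(dim), seq_len(dim), drop = FALSE]

  running_hess <- function(z, u, t) {
    H <- H_run_const
    if (!is.null(cost$extra_running)) {
      fn <- function(x) {
        s <- unpack(x[seq_len(dim)])
        cost$extra_running(s$m, s$P, x[dim + seq_along(u)], t)
      }
      H <- H + fd_hess(fn, c(z, u))
    }
    H
  }
  terminal_hess <- function(z) {
    H <- H_term_const
    if (!is.null(cost$extra_terminal)) {
      fn <- function(x) {
        s <- unpack(x[seq_len(dim)])
        cost$extra_terminal(s$m, s$P)
      }
      H <- H + fd_hess(fn, z)
    }
    H
  }

  structure(list(
    problem = problem, dim = dim, variant = variant, split = split,
    factorized = factorized && !reduced, reduced = reduced,
    rhs = rhs, z0 = z0, unpack = unpack, layout = layout,
    z_lower = z_lower, z_upper = z_upper, l_floor = l_floor,
    running = running, terminal = terminal,
    running_grad = running_grad, terminal_grad = terminal_grad,
    running_hess = running_hess, terminal_hess = terminal_hess,
    hess_const = !has_extra
  ), class = "usooc_augmented")
}

running_reference <- function(cost, t, n) {
  if (is.null(cost$state_reference)) return(rep(0, n))
  if (is.function(cost$state_reference)) cost$state_reference(t) else cost$state_reference
}

# reciprocal condition estimate for a PSD matrix (0 when singular)
rcond_psd <- function(M) {
  ev <- eigen(symm(M), symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' Covariance from the cross-covariance under a deterministic start
#'
#' For an affine drift with no diffusion and a deterministic initial state
#' (`P0 = 0`, `D(0) = 0`), the state covariance is determined by the
#' cross-covariance alone: `P(t) = D(t) Sigma^-1 D(t)'`.
#'
#' @param D cross-covariance matrix (n x p).
#' @param sigma parameter covariance (p x p, invertible).
#' @return the implied n x n state covariance (symmetric PSD).
#' @export
reduce_deterministic_init <- function(D, sigma) {
  D <- as.matrix(D)
  sigma <- as.matrix(sigma)
  if (rcond_psd(sigma) < 1e-12) {
    stop("Sigma is singular: use the full covariance propagation", call. = FALSE)
  }
  symm(D %*% solve(sigma, t(D)))
}

#' Expected cost of an augmented trajectory
#'
#' Evaluates the mean/covariance cost
#' `phi(m(T), P(T)) + int l(m, P, u, t) dt` by trapezoidal quadrature on the
#' trajectory grid, with the trace terms `tr(Q P)` / `tr(Qf P(T))` included.
#'
#' @param aug a `usooc_augmented` object.
#' @param Z augmented states, `dim x N` matrix (one column per node).
#' @param U controls, `m x N` matrix.
#' @param times grid times (length N).
#' @return scalar expected cost.
#' @export
mean_cov_cost <- function(aug, Z, U, times) {
  N <- length(times)
  if (ncol(Z) != N || ncol(U) != N) {
    stop("Z and U must have one column per grid node (", N, ")", call. = FALSE)
  }
  w <- trapezoid_weights(times)
  run <- vapply(seq_len(N), function(k) aug$running(Z[, k], U[, k], times[k]),
                numeric(1))
  sum(w * run) + aug$terminal(Z[, N])
}

#' Integrate the augmented ODE under a fixed control
#'
#' Fixed-step classical Runge-Kutta integration of the augmented dynamics with
#' the control interpolated linearly between grid nodes. Used to generate
#' cold-start guesses, verify collocation feasibility, and compare moment
#' predictions against Monte-Carlo estimates.
#'
#' @param aug a `usooc_augmented` object.
#' @param U control matrix (`m x N`) on `times`, or a `function(t)` control.
#' @param times output grid.
#' @param substeps internal RK4 substeps per grid interval.
#' @return `dim x N` matrix of augmented states on `times`.
#' @export
propagate_augmented <- function(aug, U, times, substeps = 4) {
  N <- length(times)
  ufun <- if (is.function(U)) U else control_interpolant(U, times)
  Z <- matrix(0, aug$dim, N)
  Z[, 1] <- aug$z0
  z <- aug$z0
  for (k in seq_len(N - 1)) {
    h <- (times[k + 1] - times[k]) / substeps
    t <- times[k]
    for (s in seq_len(substeps)) {
      k1 <- aug$rhs(z, ufun(t), t)
      k2 <- aug$rhs(z + h / 2 * k1, ufun(t + h / 2), t + h / 2)
      k3 <- aug$rhs(z + h / 2 * k2, ufun(t + h / 2), t + h / 2)
      k4 <- aug$rhs(z + h * k3, ufun(t + h), t + h)
      z <- z + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    Z[, k + 1] <- z
  }
  Z
}

# piecewise-linear control interpolant over grid nodes
control_interpolant <- function(U, times) {
  U <- as.matrix(U)
  function(t) {
    t <- min(max(t, times[1]), times[length(times)])
    apply(U, 1, function(row) stats::approx(times, row, xout = t)$y)
  }
}

#' Tidy an augmented trajectory into a long tibble
#'
#' @param aug a `usooc_augmented` object.
#' @param Z augmented states (`dim x N`).
#' @param times grid times.
#' @return a tibble with columns `t`, the mean components `m_i`, the
#'   covariance entries `P_i_j` (lower triangle) and the cross-covariance
#'   entries `D_i_j`.
#' @export
tidy_augmented <- function(aug, Z, times) {
  n <- aug$problem$n; p <- aug$problem$p
  rows <- lapply(seq_along(times), function(k) {
    s <- aug$unpack(Z[, k])
    vals <- c(s$m, ltri_pack(s$P), as.numeric(s$D))
    names(vals) <- c(paste0("m_", seq_len(n)), ltri_names("P", n),
                     paste0("D_", rep(seq_len(n), p), "_", rep(seq_len(p), each = n)))
    tibble::as_tibble_row(c(t = times[k], as.list(vals)))
  })
  dplyr::bind_rows(rows)
}

ltri_names <- function(prefix, n) {
  idx <- which(lower.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  paste0(prefix, "_", idx[, 1], "_", idx[, 2])
}
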