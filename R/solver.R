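#' Transcribe an augmented ODE into a nonlinear program
#'
#' Direct transcription by trapezoidal collocation: states and controls live
#' on the same grid, the dynamics enter as defect equality constraints
#' `z[k+1] - z[k] - h/2 (rhs[k] + rhs[k+1]) = 0`, the objective is the
#' mean/covariance cost evaluated by trapezoidal quadrature on the same grid,
#' and control bounds plus factor-diagonal floors become box constraints.
#' The initial augmented state is substituted (not a decision variable);
#' the control is piecewise-linear on the grid.
#'
#' @param aug a `usooc_augmented` object.
#' @param times strictly increasing grid from 0 to the horizon (>= 10 nodes).
#' @param terminal optional terminal equality constraint as
#'   `list(fun = function(zT) ..., jac = function(zT) ...)`; by default it is
#'   derived from the problem's `terminal_mean` specification.
#' @param tie_eps weight of a linear effort tie-break on lower-bounded control
#'   channels (quadratic effort alone leaves the bound multipliers of resting
#'   redundant actuators degenerate).
#' @return an object of class `usooc_nlp` with objective, gradient,
#'   constraint and sparse-Jacobian callbacks plus the decision-vector layout.
#' @export
transcribe <- function(aug, times, terminal = NULL, tie_eps = 1e-6) {
  problem <- aug$problem
  nz <- aug$dim
  nu <- problem$m
  N <- length(times)
  if (N < 10) stop("grid must have at least 10 nodes", call. = FALSE)
  if (any(diff(times) <= 0)) stop("grid times must be strictly increasing", call. = FALSE)
  h <- diff(times)
  w_quad <- trapezoid_weights(times)

  # a control channel that is unbounded and does not enter the cost would
  # make the NLP unbounded
  Rdiag <- diag(as.matrix(problem$cost$R))
  free <- !is.finite(problem$control_bounds$lower) &
    !is.finite(problem$control_bounds$upper)
  if (any(free & Rdiag <= 0)) {
    stop("control channel ", which(free & Rdiag <= 0)[1],
         " is unbounded and has zero effort weight", call. = FALSE)
  }

  if (is.null(terminal) && !is.null(aug$terminal_constraint)) {
    terminal <- aug$terminal_constraint
  }
  if (is.null(terminal) && !is.null(problem$terminal_mean)) {
    tm <- problem$terminal_mean
    idx <- tm$idx
    val <- tm$value
    Tmat <- matrix(0, length(idx), nz)
    Tmat[cbind(seq_along(idx), aug$layout$idx_m[idx])] <- 1
    terminal <- list(fun = function(zT) zT[aug$layout$idx_m[idx]] - val,
                     jac = function(zT) Tmat)
  }
  q_term <- if (is.null(terminal)) 0 else length(terminal$fun(aug$z0))

  nw <- (N - 1) * nz + N * nu
  ncon <- (N - 1) * nz + q_term
  idx_z <- function(k) (k - 2) * nz + seq_len(nz)        # k >= 2
  idx_u <- function(k) (N - 1) * nz + (k - 1) * nu + seq_len(nu)

  w_pack <- function(Z, U) c(as.numeric(Z[, -1, drop = FALSE]), as.numeric(U))
  w_unpack <- function(w) {
    Z <- cbind(aug$z0, matrix(w[seq_len((N - 1) * nz)], nz, N - 1))
    U <- matrix(w[(N - 1) * nz + seq_len(N * nu)], nu, N)
    list(Z = Z, U = U)
  }

  lower <- c(rep(aug$z_lower, N - 1), rep(problem$control_bounds$lower, N))
  upper <- c(rep(aug$z_upper, N - 1), rep(problem$control_bounds$upper, N))

  eval_F <- function(Z, U) {
    matrix(vapply(seq_len(N), function(k) aug$rhs(Z[, k], U[, k], times[k]),
                  numeric(nz)), nz, N)
  }

  cons_full <- function(Z, U, F = NULL) {
    if (is.null(F)) F <- eval_F(Z, U)
    defects <- Z[, -1, drop = FALSE] - Z[, -N, drop = FALSE] -
      rep(h / 2, each = nz) * (F[, -N, drop = FALSE] + F[, -1, drop = FALSE])
    out <- as.numeric(defects)
    if (q_term > 0) out <- c(out, terminal$fun(Z[, N]))
    out
  }

  # sparse Jacobian pattern (triplets, fixed order): for each interval k,
  # blocks wrt z_k (k>=2), z_{k+1}, u_k, u_{k+1}; then terminal rows wrt z_N
  trip_i <- integer(0); trip_j <- integer(0)
  for (k in seq_len(N - 1)) {
    rows <- (k - 1) * nz + seq_len(nz)
    if (k >= 2) {
      trip_i <- c(trip_i, rep(rows, nz)); trip_j <- c(trip_j, rep(idx_z(k), each = nz))
    }
    trip_i <- c(trip_i, rep(rows, nz)); trip_j <- c(trip_j, rep(idx_z(k + 1), each = nz))
    trip_i <- c(trip_i, rep(rows, nu)); trip_j <- c(trip_j, rep(idx_u(k), each = nz))
    trip_i <- c(trip_i, rep(rows, nu)); trip_j <- c(trip_j, rep(idx_u(k + 1), each = nz))
  }
  if (q_term > 0) {
    rows <- (N - 1) * nz + seq_len(q_term)
    trip_i <- c(trip_i, rep(rows, nz)); trip_j <- c(trip_j, rep(idx_z(N), each = q_term))
  }
  Ib <- diag(nz)

  node_jacobians <- function(Z, U) {
    Fz <- array(0, c(nz, nz, N)); Fu <- array(0, c(nz, nu, N))
    for (k in seq_len(N)) {
      z <- Z[, k]; u <- U[, k]; t <- times[k]
      for (j in seq_len(nz)) {
        s <- 1e-6 * (1 + abs(z[j]))
        zp <- z; zp[j] <- zp[j] + s
        zm <- z; zm[j] <- zm[j] - s
        # keep factor diagonal above zero when perturbing downwards
        Fz[, j, k] <- (aug$rhs(zp, u, t) - aug$rhs(zm, u, t)) / (2 * s)
      }
      for (j in seq_len(nu)) {
        s <- 1e-6 * (1 + abs(u[j]))
        up <- u; up[j] <- up[j] + s
        um <- u; um[j] <- um[j] - s
        Fu[, j, k] <- (aug$rhs(z, up, t) - aug$rhs(z, um, t)) / (2 * s)
      }
    }
    list(Fz = Fz, Fu = Fu)
  }

  jac <- function(Z, U) {
    nj <- node_jacobians(Z, U)
    vals <- numeric(0)
    pieces <- vector("list", 4 * (N - 1) + 1)
    idx <- 1
    for (k in seq_len(N - 1)) {
      hk <- h[k] / 2
      if (k >= 2) {
        pieces[[idx]] <- as.numeric(-Ib - hk * nj$Fz[, , k]); idx <- idx + 1
      }
      pieces[[idx]] <- as.numeric(Ib - hk * nj$Fz[, , k + 1]); idx <- idx + 1
      pieces[[idx]] <- as.numeric(-hk * nj$Fu[, , k]); idx <- idx + 1
      pieces[[idx]] <- as.numeric(-hk * nj$Fu[, , k + 1]); idx <- idx + 1
    }
    if (q_term > 0) {
      pieces[[idx]] <- as.numeric(terminal$jac(Z[, N])); idx <- idx + 1
    }
    vals <- unlist(pieces[seq_len(idx - 1)], use.names = FALSE)
    Matrix::sparseMatrix(i = trip_i, j = trip_j, x = vals, dims = c(ncon, nw))
  }

  # quadratic effort is gradient-free at a resting muscle, which makes the
  # lower-bound multipliers of inactive redundant actuators degenerate; a tiny
  # linear effort term breaks the tie (its weight is far below any physical
  # effect of interest)
  tie_ch <- which(is.finite(problem$control_bounds$lower))
  tie_lb <- problem$control_bounds$lower[tie_ch]

  obj_full <- function(Z, U) {
    run <- vapply(seq_len(N), function(k) aug$running(Z[, k], U[, k], times[k]),
                  numeric(1))
    tie <- if (length(tie_ch)) {
      tie_eps * sum(w_quad * colSums(U[tie_ch, , drop = FALSE] - tie_lb))
    } else 0
    sum(w_quad * run) + aug$terminal(Z[, N]) + tie
  }

  grad_obj <- function(Z, U) {
    gZ <- matrix(0, nz, N)
    gU <- matrix(0, nu, N)
    for (k in seq_len(N)) {
      rg <- aug$running_grad(Z[, k], U[, k], times[k])
      gZ[, k] <- w_quad[k] * rg$gz
      gU[, k] <- w_quad[k] * rg$gu
    }
    gZ[, N] <- gZ[, N] + aug$terminal_grad(Z[, N])
    if (length(tie_ch)) {
      gU[tie_ch, ] <- gU[tie_ch, ] + rep(tie_eps * w_quad, each = length(tie_ch))
    }
    c(as.numeric(gZ[, -1, drop = FALSE]), as.numeric(gU))
  }

  # block-diagonal Hessian of the (node-separable) objective; exact for the
  # quadratic mean/covariance costs, Gauss-Newton (eigenvalue-floored) when
  # non-quadratic extras are present
  hess_blocks <- function(Z, U) {
    nb <- nz + nu
    H <- array(0, c(nb, nb, N))
    for (k in seq_len(N)) {
      Hk <- w_quad[k] * aug$running_hess(Z[, k], U[, k], times[k])
      if (k == N) {
        Hk[seq_len(nz), seq_len(nz)] <- Hk[seq_len(nz), seq_len(nz)] +
          aug$terminal_hess(Z[, N])
      }
      if (!aug$hess_const) {
        # convexify: floor the block eigenvalues at zero
        eg <- eigen(symm(Hk), symmetric = TRUE)
        ev <- pmax(eg$values, 0)
        Hk <- eg$vectors %*% (ev * t(eg$vectors))
      }
      H[, , k] <- Hk
    }
    H
  }

  # constraint-curvature contraction: per-node Hessian of sum_i v_i F_i(z,u,t)
  # where v collects the (defect) multipliers weighting each node's rhs; this
  # is the lambda' grad2 c term of the Lagrangian Hessian
  lag_curv_blocks <- function(Z, U, lambda) {
    nb <- nz + nu
    H <- array(0, c(nb, nb, N))
    Lam <- matrix(lambda[seq_len((N - 1) * nz)], nz, N - 1)
    for (k in seq_len(N)) {
      v <- numeric(nz)
      if (k > 1) v <- v - h[k - 1] / 2 * Lam[, k - 1]
      if (k < N) v <- v - h[k] / 2 * Lam[, k]
      if (max(abs(v)) < 1e-14) next
      fn <- function(x) sum(v * aug$rhs(x[seq_len(nz)], x[nz + seq_len(nu)], times[k]))
      H[, , k] <- fd_hess(fn, c(Z[, k], U[, k]))
    }
    H
  }

  # sparse symmetric Hessian over the decision vector from per-node blocks
  blocks_to_sparse <- function(H) {
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (k in seq_len(N)) {
      cols <- c(if (k >= 2) idx_z(k) else rep(NA_integer_, nz), idx_u(k))
      keep <- !is.na(cols)
      blk <- H[keep, keep, k, drop = FALSE][, , 1]
      cs <- cols[keep]
      ii <- c(ii, rep(cs, length(cs)))
      jj <- c(jj, rep(cs, each = length(cs)))
      xx <- c(xx, as.numeric(blk))
    }
    Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nw, nw))
  }
  hess_sparse <- function(Z, U, lambda = NULL, curv = NULL) {
    H <- hess_blocks(Z, U)
    if (!is.null(curv)) {
      H <- H + curv
    } else if (!is.null(lambda)) {
      H <- H + lag_curv_blocks(Z, U, lambda)
    }
    blocks_to_sparse(H)
  }

  structure(list(
    aug = aug, times = times, N = N, nz = nz, nu = nu, nw = nw, ncon = ncon,
    q_term = q_term, lower = lower, upper = upper,
    w_pack = w_pack, w_unpack = w_unpack,
    eval_F = eval_F, cons_full = cons_full, jac = jac,
    obj_full = obj_full, grad_obj = grad_obj, hess_sparse = hess_sparse,
    lag_curv_blocks = lag_curv_blocks
  ), class = "usooc_nlp")
}

#' Solve a transcribed nonlinear program
#'
#' Sequential quadratic programming with an interior-point-style convergence
#' contract: at each iterate the equality constraints (collocation defects and
#' terminal conditions) are linearized with the analytically assembled sparse
#' Jacobian, the objective is modeled by its block-diagonal (node-separable)
#' convexified Hessian, and the resulting equality-constrained quadratic
#' subproblem is solved through one sparse KKT factorization
#' (Matrix package). Box constraints (control bounds, covariance-factor
#' floors) are handled by an active-set strategy with bound-multiplier release
#' checks, and globalization uses a backtracking line search on the l1 merit
#' function. Deterministic given identical inputs.
#'
#' @param nlp a `usooc_nlp` from [transcribe()].
#' @param w0 initial decision vector (e.g. from `nlp$w_pack(Z, U)`).
#' @param control list of solver options: `feas_tol` (default `1e-8`),
#'   `opt_tol` (default `1e-6`, relative to the objective gradient scale),
#'   `maxit` SQP iterations (default 3000), `reg0` initial Hessian
#'   regularization.
#' @return list with `w`, `cost`, `status` (`converged`, `max_iter` or
#'   `infeasible`), `iterations`, `feasibility`, `optimality`, `lambda` and a
#'   character `log`. Non-convergence is reported through `status`, never as
#'   an error.
#' @export
solve_nlp <- function(nlp, w0, control = list()) {
  ctl <- utils::modifyList(list(
    feas_tol = 1e-8, opt_tol = 1e-6, maxit = 3000, reg0 = 1e-8,
    curv_every = 1, scale = FALSE, verbose = FALSE
  ), control)

  nw <- nlp$nw; ncon <- nlp$ncon

  # optional variable and constraint-row scaling from the initial iterate:
  # each augmented coordinate and control channel is measured in units of its
  # typical magnitude, and each defect row is scaled like its coordinate.
  # Useful when coordinates span many orders of magnitude; for well-scaled
  # models it slightly loosens the effective tolerances, hence opt-in.
  if (isTRUE(ctl$scale)) {
    s00 <- nlp$w_unpack(pmin(pmax(w0, nlp$lower), nlp$upper))
    zscale <- pmax(apply(abs(s00$Z), 1, max), 1e-2)
    urange <- nlp$upper[(nlp$N - 1) * nlp$nz + seq_len(nlp$nu)] -
      nlp$lower[(nlp$N - 1) * nlp$nz + seq_len(nlp$nu)]
    uscale <- pmax(apply(abs(s00$U), 1, max),
                   ifelse(is.finite(urange), urange, 0), 0.1)
  } else {
    zscale <- rep(1, nlp$nz)
    uscale <- rep(1, nlp$nu)
  }
  sw <- c(rep(zscale, nlp$N - 1), rep(uscale, nlp$N))
  sr <- c(rep(zscale, nlp$N - 1), rep(1, nlp$q_term))
  Dw <- Matrix::Diagonal(x = sw)
  Drinv <- Matrix::Diagonal(x = 1 / sr)
  nlp_raw <- nlp
  nlp <- list(
    N = nlp_raw$N, nz = nlp_raw$nz, nu = nlp_raw$nu, nw = nw, ncon = ncon,
    q_term = nlp_raw$q_term,
    lower = nlp_raw$lower / sw, upper = nlp_raw$upper / sw,
    w_unpack = function(wt) nlp_raw$w_unpack(wt * sw),
    eval_F = nlp_raw$eval_F,
    cons_full = function(Z, U, F = NULL) nlp_raw$cons_full(Z, U, F) / sr,
    jac = function(Z, U) Drinv %*% nlp_raw$jac(Z, U) %*% Dw,
    grad_obj = function(Z, U) nlp_raw$grad_obj(Z, U) * sw,
    obj_full = nlp_raw$obj_full,
    lag_curv_blocks = function(Z, U, lambda) {
      nlp_raw$lag_curv_blocks(Z, U, lambda / sr)
    },
    hess_sparse = function(Z, U, lambda = NULL, curv = NULL) {
      Dw %*% nlp_raw$hess_sparse(Z, U, lambda = lambda, curv = curv) %*% Dw
    }
  )
  w0 <- w0 / sw

  # clamp into the box; state coordinates stay strictly interior to their
  # floors (the barrier needs positive distances)
  state_margin <- c(rep(1e-7, (nlp$N - 1) * nlp$nz), rep(0, nlp$N * nlp$nu))
  lo_int <- ifelse(is.finite(nlp$lower), nlp$lower + state_margin, nlp$lower)
  w <- pmin(pmax(w0, lo_int), nlp$upper)
  lambda <- rep(0, ncon)
  log <- character(0)
  status <- "max_iter"
  nu_merit <- 1

  parts <- function(w) {
    s <- nlp$w_unpack(w)
    F <- nlp$eval_F(s$Z, s$U)
    list(s = s, cvec = nlp$cons_full(s$Z, s$U, F),
         obj = nlp$obj_full(s$Z, s$U))
  }
  p <- parts(w)
  g <- nlp$grad_obj(p$s$Z, p$s$U)
  obj_scale <- max(1, max(abs(g)))
  merit <- function(p, wv) {
    p$obj / obj_scale + bar_val(wv) + nu_merit * sum(abs(p$cvec))
  }
  # nonmonotone reference memory stores the merit COMPONENTS of recent
  # accepted iterates, so the reference stays coherent when the penalty
  # weight changes
  hist_f <- numeric(0)
  hist_c <- numeric(0)

  feas <- max(abs(p$cvec)); opt <- Inf
  delta <- ctl$reg0
  it <- 0
  release_tol <- 10 * ctl$opt_tol
  curv_cache <- NULL
  f_prev <- NA_real_
  stall_count <- 0
  # augmented-state coordinates (vs control coordinates): state bounds (the
  # covariance-factor floors) are handled by a weak log-barrier plus a
  # fraction-to-boundary rule, never by active-set pinning -- pinning a state
  # coordinate can make the linearized defects inconsistent and blow up the
  # multipliers. Controls are pinned/released by multiplier sign as usual.
  is_state <- c(rep(TRUE, (nlp$N - 1) * nlp$nz), rep(FALSE, nlp$N * nlp$nu))
  sb <- which(is_state & is.finite(nlp$lower))
  tau_b <- 0
  bar_val <- function(w) {
    if (!length(sb)) return(0)
    -tau_b * sum(log(pmax(w[sb] - nlp$lower[sb], 1e-300)))
  }
  bar_grad <- function(w) {
    gb <- numeric(nw)
    if (length(sb)) gb[sb] <- -tau_b / pmax(w[sb] - nlp$lower[sb], 1e-300)
    gb
  }
  bar_hess_diag <- function(w) {
    hb <- numeric(nw)
    if (length(sb)) hb[sb] <- tau_b / pmax(w[sb] - nlp$lower[sb], 1e-300)^2
    hb
  }
  # active set: variables held at a bound (membership evolves by
  # fraction-to-boundary hits and single-coordinate multiplier releases)
  active <- w <= nlp$lower + 1e-11 | w >= nlp$upper - 1e-11

  while (it < ctl$maxit) {
    it <- it + 1
    J <- nlp$jac(p$s$Z, p$s$U)
    g <- nlp$grad_obj(p$s$Z, p$s$U) / obj_scale
    # Lagrangian Hessian (multipliers rescaled to the unscaled objective);
    # the constraint-curvature contraction is the expensive block for larger
    # models and is refreshed on a small cycle
    if (is.null(curv_cache) || it %% ctl$curv_every == 1 || ctl$curv_every == 1) {
      curv_cache <- nlp$lag_curv_blocks(p$s$Z, p$s$U, lambda * obj_scale)
    }
    B <- nlp$hess_sparse(p$s$Z, p$s$U, curv = curv_cache) / obj_scale
    g <- g + bar_grad(w)
    B <- B + Matrix::Diagonal(x = bar_hess_diag(w))

    gL <- g + as.numeric(Matrix::crossprod(J, lambda))
    at_lo <- w <= nlp$lower + 1e-11
    at_hi <- w >= nlp$upper - 1e-11
    # working set from the bound-multiplier signs under the current duals: a
    # coordinate at its lower bound stays pinned while the Lagrangian gradient
    # points inward; mis-pinned coordinates are released wholesale (the inner
    # batch re-pinning below absorbs any chatter without taking bad steps)
    active <- (at_lo & gL > -release_tol) | (at_hi & gL < release_tol)

    feas <- max(abs(p$cvec))
    free <- which(!active)
    opt <- if (length(free)) max(abs(gL[free])) else 0
    opt_tol_eff <- ctl$opt_tol * (1 + abs(p$obj) / obj_scale)
    if (feas <= ctl$feas_tol && opt > opt_tol_eff && length(free)) {
      # the running multipliers lag one step behind; refresh them by a
      # least-squares fit before concluding non-optimality
      Jf <- J[, free, drop = FALSE]
      lam_ls <- tryCatch(as.numeric(Matrix::solve(
        Matrix::tcrossprod(Jf) + 1e-10 * Matrix::Diagonal(ncon),
        -Jf %*% g[free])), error = function(e) NULL)
      if (!is.null(lam_ls) && all(is.finite(lam_ls))) {
        gL_ls <- g + as.numeric(Matrix::crossprod(J, lam_ls))
        opt_ls <- max(abs(gL_ls[free]))
        if (opt_ls < opt) {
          opt <- opt_ls
          lambda <- lam_ls
          gL <- gL_ls
        }
      }
    }
    if (feas <= ctl$feas_tol && opt <= opt_tol_eff) {
      status <- "converged"
      break
    }
    # stationarity acceptance: feasible, objective numerically stationary and
    # the dual residual within two orders of the target (the finite-difference
    # constraint Jacobians floor the attainable dual precision)
    if (feas <= ctl$feas_tol && is.finite(f_prev) &&
        abs(p$obj - f_prev) <= 1e-11 * (1 + abs(p$obj)) &&
        opt <= 100 * ctl$opt_tol * (1 + abs(p$obj) / obj_scale)) {
      stall_count <- stall_count + 1
      if (stall_count >= 5) {
        status <- "converged"
        break
      }
    } else {
      stall_count <- 0
    }
    f_prev <- p$obj

    # KKT solve over free variables (symmetrically equilibrated for the wide
    # dynamic range the covariance-factor dynamics can produce), with
    # regularization escalation. An inner active-set loop batch-pins every
    # coordinate the step would immediately drive across its bound and
    # re-solves, so that many bounds can activate in a single iteration.
    kkt_solve <- function(free, gvec, cvec) {
      Jf <- J[, free, drop = FALSE]
      for (try in 1:12) {
        K <- rbind(
          cbind(B[free, free, drop = FALSE] + delta * Matrix::Diagonal(length(free)),
                Matrix::t(Jf)),
          cbind(Jf, -1e-12 * Matrix::Diagonal(ncon))
        )
        rhs <- c(-gvec[free], -cvec)
        sc <- 1 / sqrt(pmax(col_abs_max(K), 1e-10))
        Ks <- Matrix::Diagonal(x = sc) %*% K %*% Matrix::Diagonal(x = sc)
        sol <- tryCatch(sc * as.numeric(Matrix::solve(Ks, sc * rhs)),
                        error = function(e) NULL)
        if (!is.null(sol) && all(is.finite(sol))) return(sol)
        delta <<- max(delta * 100, 1e-6)
      }
      NULL
    }
    pinned <- active
    d <- NULL; lambda_new <- NULL; alpha_max <- 1
    for (as_it in 1:12) {
      free <- which(!pinned)
      if (!length(free)) break
      step <- kkt_solve(free, g, p$cvec)
      if (is.null(step)) break
      d <- numeric(nw)
      d[free] <- step[seq_along(free)]
      lambda_new <- step[length(free) + seq_len(ncon)]
      # crossing fraction per coordinate; state coordinates keep a strictly
      # interior margin (they are never allowed to touch their floor)
      frac <- rep(Inf, nw)
      neg <- which(d < 0 & is.finite(nlp$lower))
      frac[neg] <- (nlp$lower[neg] - w[neg]) / d[neg]
      pos <- which(d > 0 & is.finite(nlp$upper))
      frac[pos] <- (nlp$upper[pos] - w[pos]) / d[pos]
      alpha_max <- max(min(frac, 1), 0)
      hitters <- which(frac < 0.9)
      if (!length(hitters)) {
        # active-set release inside the subproblem: a pinned bound whose
        # quadratic-model multiplier has the wrong sign is released (its step
        # then moves inward, so it cannot be re-pinned by the same loop)
        gQP <- g + as.numeric(B %*% d) +
          as.numeric(Matrix::crossprod(J, lambda_new))
        rel <- which(pinned & ((at_lo & gQP < -1e-8 * (1 + opt)) |
                                 (at_hi & gQP > 1e-8 * (1 + opt))))
        if (length(rel) && as_it < 12) {
          pinned[rel] <- FALSE
          next
        }
        break
      }
      pinned[hitters] <- TRUE
    }
    if (is.null(d) || is.null(lambda_new)) { status <- "max_iter"; break }
    active <- pinned

    # consistency check: a pinned set can make the linearized defects
    # unsatisfiable (the dynamics may force a covariance-factor floor
    # upward). The regularized KKT then "solves" with exploding multipliers;
    # fall back to an elastic penalty step that trades feasibility against
    # the bounds smoothly and leaves the multipliers untouched.
    res <- max(abs(as.numeric(J[, free, drop = FALSE] %*% d[free]) + p$cvec))
    if (res > max(1e-7, 1e-2 * max(abs(p$cvec))) ||
        max(abs(lambda_new)) > 1e8) {
      rho_e <- min(1e6, max(1e2, 10 / max(max(abs(p$cvec)), 1e-6)))
      Jf <- J[, free, drop = FALSE]
      Be <- B[free, free, drop = FALSE] +
        (delta + 1e-8) * Matrix::Diagonal(length(free)) +
        rho_e * Matrix::crossprod(Jf)
      ge <- g[free] + rho_e * as.numeric(Matrix::crossprod(Jf, p$cvec))
      sc <- 1 / sqrt(pmax(col_abs_max(Be), 1e-10))
      de <- tryCatch(
        sc * as.numeric(Matrix::solve(
          Matrix::Diagonal(x = sc) %*% Be %*% Matrix::Diagonal(x = sc),
          -sc * ge)),
        error = function(e) NULL)
      if (!is.null(de) && all(is.finite(de))) {
        d <- numeric(nw)
        d[free] <- de
        lambda_new <- lambda
        frac <- rep(Inf, nw)
        neg <- which(d < 0 & is.finite(nlp$lower))
        frac[neg] <- (nlp$lower[neg] - w[neg]) / d[neg]
        pos <- which(d > 0 & is.finite(nlp$upper))
        frac[pos] <- (nlp$upper[pos] - w[pos]) / d[pos]
        alpha_max <- max(min(frac, 1), 0)
      }
    }

    # l1 merit line search; the penalty tracks the multiplier scale in both
    # directions (a transient multiplier spike must not freeze the penalty
    # at a level that blocks objective progress forever)
    nu_need <- 1.2 * max(abs(lambda_new)) + 1e-3
    nu_merit <- if (nu_need > nu_merit) nu_need else max(nu_need, nu_merit / 2)
    phi0 <- merit(p, w)
    Dphi <- sum(g * d) - nu_merit * sum(abs(p$cvec))
    if (Dphi > -1e-14 * (1 + abs(phi0)) && feas <= ctl$feas_tol) {
      # not a descent direction for the merit function: stiffen the model
      delta <- max(delta * 100, 1e-6)
      if (delta > 1e8) { status <- "max_iter"; break }
      next
    }
    # nonmonotone reference: the worst of the last few accepted iterates,
    # re-evaluated under the current penalty weight
    phi_ref <- if (length(hist_f)) {
      max(max(hist_f + nu_merit * hist_c), phi0)
    } else {
      phi0
    }
    alpha <- alpha_max
    accepted <- FALSE
    soc_tried <- FALSE
    if (alpha > 1e-14) {
      for (ls in 1:30) {
        w_try <- pmin(pmax(w + alpha * d, nlp$lower), nlp$upper)
        p_try <- tryCatch(parts(w_try), error = function(e) NULL)
        ok <- !is.null(p_try) && all(is.finite(p_try$cvec)) && is.finite(p_try$obj)
        if (ok && merit(p_try, w_try) <= phi_ref + 1e-4 * alpha * min(Dphi, 0)) {
          accepted <- TRUE
          break
        }
        if (ok && !soc_tried && alpha == alpha_max) {
          # second-order correction: a full step rejected because of the
          # constraint curvature gets one Newton correction on the residual
          soc_tried <- TRUE
          soc <- kkt_solve(free, numeric(nw), p_try$cvec)
          if (!is.null(soc)) {
            dcor <- numeric(nw)
            dcor[free] <- soc[seq_along(free)]
            w_soc <- pmin(pmax(w_try + dcor, nlp$lower), nlp$upper)
            p_soc <- tryCatch(parts(w_soc), error = function(e) NULL)
            if (!is.null(p_soc) && all(is.finite(p_soc$cvec)) &&
                is.finite(p_soc$obj) &&
                merit(p_soc, w_soc) <= phi_ref + 1e-4 * alpha * min(Dphi, 0)) {
              w_try <- w_soc
              p_try <- p_soc
              accepted <- TRUE
              break
            }
          }
        }
        alpha <- alpha / 2
      }
    }
    if (!accepted) {
      # could not make progress along this direction; stiffen the model
      delta <- max(delta * 100, 1e-6)
      if (delta > 1e8) { status <- "max_iter"; break }
      next
    }
    w <- w_try
    # snap near-bound coordinates still heading into the bound, so that a
    # geometric approach cannot throttle the step length indefinitely
    snap_lo <- d < 0 & (w - nlp$lower) < 1e-9 * (1 + abs(nlp$lower))
    snap_hi <- d > 0 & (nlp$upper - w) < 1e-9 * (1 + abs(nlp$upper))
    if (any(snap_lo) || any(snap_hi)) {
      w[snap_lo] <- nlp$lower[snap_lo]
      w[snap_hi] <- nlp$upper[snap_hi]
      p_try <- parts(w)
    }
    lambda <- lambda_new
    p <- p_try
    hist_f <- c(utils::tail(hist_f, 4), p$obj / obj_scale + bar_val(w))
    hist_c <- c(utils::tail(hist_c, 4), sum(abs(p$cvec)))
    # a micro step that survives the line search but moves almost nowhere signals
    # an over-optimistic local model: stiffen instead of relaxing
    if (alpha < 1e-3) {
      delta <- min(max(delta * 10, 1e-6), 1e8)
    } else {
      delta <- max(delta / 10, ctl$reg0)
    }
    if (isTRUE(ctl$verbose) || it <= 200) {
      log <- c(log, sprintf(
        "it %03d: f=%.6e feas=%.3e opt=%.3e alpha=%.2g active=%d delta=%.1e",
        it, p$obj, max(abs(p$cvec)), opt, alpha, sum(active), delta))
      if (isTRUE(ctl$verbose)) message(log[length(log)])
    }
  }
  feas <- max(abs(p$cvec))
  if (status != "converged" && feas > 1e-4) status <- "infeasible"

  list(w = w * sw, cost = p$obj, status = status, iterations = it,
       feasibility = feas, optimality = opt, lambda = lambda / sr, log = log)
}

#' Solve an uncertain optimal open-loop control problem
#'
#' End-to-end driver: validates the problem, builds the factorized augmented
#' ODE, transcribes on a uniform grid, generates a cold-start guess (controls
#' at their lower bounds plus a small constant, augmented states from forward
#' integration of the guess), and solves the resulting nonlinear program.
#'
#' @param problem a `usooc_problem`.
#' @param N number of collocation nodes (defaults to the model's preset, else
#'   101).
#' @param times optional explicit grid (overrides `N`); see
#'   [collocation_grid()] for graded grids resolving initial boundary layers.
#' @param guess optional warm start: a previous `usooc_solution` or a
#'   `list(Z =, U =)` on the same grid.
#' @param control solver options passed to [solve_nlp()].
#' @param aug optionally a prebuilt `usooc_augmented` (must match `problem`).
#' @return an object of class `usooc_solution`: grid `times`, control matrix
#'   `U` (m x N), augmented states `Z` (dim x N), `cost`, `status`,
#'   `iterations`, `feasibility` and the solver log.
#' @examples
#' \donttest{
#' prob <- make_toy_problem(alpha = 0.5)
#' sol <- solve_usooc(prob, N = 41)
#' glance(sol)
#' }
#' @export
solve_usooc <- function(problem, N = NULL, times = NULL, guess = NULL,
                        control = list(), aug = NULL) {
  if (!isTRUE(problem$validated)) problem <- validate_problem(problem)
  if (is.null(times)) {
    if (is.null(N)) N <- if (!is.null(problem$default_N)) problem$default_N else 101
    times <- seq(0, problem$horizon, length.out = N)
  } else {
    N <- length(times)
  }
  if (is.null(aug)) {
    aug <- build_augmented(problem, factorized = problem$factorize_covariance)
  }
  nlp <- transcribe(aug, times)

  # model-declared cold-start homotopy: solve a sequence of simpler instances
  # (e.g. without signal-dependent noise, or the deterministic reach) and
  # warm-start from the last converged one
  if (is.null(guess) && !is.null(problem$homotopy)) {
    stage_control <- utils::modifyList(control, list(
      maxit = min(if (is.null(control$maxit)) 150 else control$maxit, 150),
      curv_every = 3))
    for (simpler in problem$homotopy()) {
      simpler$homotopy <- NULL
      stage <- solve_usooc(simpler, N = N, times = times, guess = guess,
                           control = stage_control)
      if (stage$status == "converged") guess <- stage
    }
  }

  if (is.null(guess)) {
    u_cold <- if (!is.null(problem$guess_control)) {
      problem$guess_control
    } else {
      ifelse(is.finite(problem$control_bounds$lower),
             problem$control_bounds$lower + 1e-3, 0)
    }
    U0 <- matrix(u_cold, problem$m, N)
    Z0 <- tryCatch(cold_start_states(problem, aug, U0, times),
                   error = function(e) NULL)
    # an open-loop-unstable model can blow up under the holding control; fall
    # back to a constant profile and let the defects pull it in
    if (is.null(Z0) || any(!is.finite(Z0)) ||
        max(abs(Z0)) > 1e3 * (1 + max(abs(aug$z0)))) {
      Z0 <- matrix(aug$z0, aug$dim, N)
    }
  } else {
    guess_layout <- NULL
    if (inherits(guess, "usooc_solution")) {
      guess_layout <- guess$aug$layout
      guess <- if (!is.null(guess$times) && !isTRUE(all.equal(guess$times, times))) {
        resample_solution(guess, times)
      } else {
        list(Z = guess$Z, U = guess$U)
      }
    }
    U0 <- matrix(guess$U, problem$m, N)
    # keep warm-started controls strictly inside their bounds (a control
    # pinned exactly at a bound starts with an uninformative multiplier)
    lo <- problem$control_bounds$lower
    hi <- problem$control_bounds$upper
    U0 <- pmax(U0, ifelse(is.finite(lo), lo + 1e-3, -Inf))
    U0 <- pmin(U0, ifelse(is.finite(hi), hi - 1e-3, Inf))
    Z0 <- guess$Z
    # a warm start from a differently structured instance (e.g. another
    # uncertainty level where some augmented blocks degenerate away) is
    # adapted blockwise: matching blocks are copied, new blocks start from
    # their initial values
    if (!is.null(Z0) && nrow(Z0) != aug$dim && !is.null(guess_layout)) {
      Znew <- matrix(aug$z0, aug$dim, N)
      for (blk in c("idx_m", "idx_L", "idx_P2", "idx_D")) {
        io <- guess_layout[[blk]]; in_ <- aug$layout[[blk]]
        if (length(io) && length(io) == length(in_)) {
          Znew[in_, ] <- Z0[io, , drop = FALSE]
        }
      }
      Z0 <- Znew
    }
    if (is.null(Z0) || nrow(Z0) != aug$dim) {
      Z0 <- tryCatch(cold_start_states(problem, aug, U0, times),
                     error = function(e) NULL)
      if (is.null(Z0) || any(!is.finite(Z0))) Z0 <- matrix(aug$z0, aug$dim, N)
    }
  }
  Z0 <- pmin(pmax(Z0, aug$z_lower), aug$z_upper)

  res <- solve_nlp(nlp, nlp$w_pack(Z0, U0), control = control)
  s <- nlp$w_unpack(res$w)
  structure(list(
    problem = problem, aug = aug, times = times, U = s$U, Z = s$Z,
    cost = res$cost, status = res$status, iterations = res$iterations,
    feasibility = res$feasibility, optimality = res$optimality,
    solver_log = res$log
  ), class = "usooc_solution")
}

#' @export
print.usooc_solution <- function(x, ...) {
  cat("<usooc_solution>", x$problem$name, "\n")
  cat("  status:", x$status, "| cost:", signif(x$cost, 6),
      "| feasibility:", signif(x$feasibility, 3),
      "| iterations:", x$iterations, "\n")
  invisible(x)
}

# Cold-start state trajectories: integrate the (robust) unfactorized
# augmentation and refactor the covariance node-wise -- direct integration of
# the triangular-factor ODE can be stiff near rank-deficient covariances.
cold_start_states <- function(problem, aug, U0, times) {
  if (!isTRUE(aug$factorized)) return(propagate_augmented(aug, U0, times))
  augu <- build_augmented(problem, factorized = FALSE)
  Zu <- propagate_augmented(augu, U0, times)
  Z <- matrix(0, aug$dim, length(times))
  for (k in seq_along(times)) {
    s <- augu$unpack(Zu[, k])
    zk <- numeric(aug$dim)
    zk[aug$layout$idx_m] <- s$m
    if (length(aug$layout$idx_L)) {
      L <- chol_lower(s$P1, floor = 1e-10)
      diag(L) <- pmax(diag(L), aug$l_floor)
      zk[aug$layout$idx_L] <- ltri_pack(L)
    }
    if (length(aug$layout$idx_D)) zk[aug$layout$idx_D] <- as.numeric(s$D)
    Z[, k] <- zk
  }
  Z[, 1] <- aug$z0
  Z
}

#' Collocation grid, optionally graded toward the initial time
#'
#' Stabilization problems with substantial initial-state covariance have a
#' steep initial impedance boundary layer (the optimal stiffness decays from a
#' large initial value on a time scale shorter than a uniform grid step). A
#' power-graded grid `T (i/(N-1))^grading` concentrates nodes there and lets
#' the transcription resolve the layer.
#'
#' @param horizon horizon T.
#' @param N number of nodes.
#' @param grading power `>= 1`; 1 gives the uniform grid.
#' @return increasing vector of `N` times from 0 to `horizon`.
#' @export
collocation_grid <- function(horizon, N, grading = 1) {
  horizon * seq(0, 1, length.out = N)^grading
}

#' Resample a solution onto a new grid (for warm starts)
#'
#' Linearly interpolates the control and augmented-state trajectories of a
#' solution onto a different collocation grid, e.g. to warm-start a solve on
#' a refined or graded grid.
#'
#' @param sol a `usooc_solution`.
#' @param times new grid.
#' @return `list(Z =, U =)` suitable as the `guess` of [solve_usooc()].
#' @export
resample_solution <- function(sol, times) {
  res <- function(M) {
    t(vapply(seq_len(nrow(M)),
             function(i) stats::approx(sol$times, M[i, ], xout = times)$y,
             numeric(length(times))))
  }
  list(Z = res(sol$Z), U = res(sol$U))
}

#' Continuation over a schedule of problem instances
#'
#' Solves an ordered list of related problems (typically increasing
#' disturbance probability), warm-starting each instance from its
#' predecessor's solution. The first instance must converge from a cold
#' start; later non-convergences are reported but do not abort the sweep.
#'
#' @param problems list of `usooc_problem`s, or a factory `function(alpha)`
#'   combined with `alphas`.
#' @param alphas numeric vector of disturbance probabilities (when `problems`
#'   is a factory).
#' @param N nodes per instance (shared grid).
#' @param control solver options.
#' @param warm_start reuse the previous solution as initial guess.
#' @param fallback_factory optional `function(alpha)` returning a simpler
#'   related problem (e.g. the same model without signal-dependent noise);
#'   when an instance fails both warm- and cold-started, the simpler instance
#'   is solved and its solution used as the warm start.
#' @return list of `usooc_solution`s, with a `summary` attribute tibble
#'   (one row per instance: alpha if known, cost, status).
#' @export
continuation_solve <- function(problems, alphas = NULL, N = NULL,
                               control = list(), warm_start = TRUE,
                               fallback_factory = NULL) {
  if (is.function(problems)) {
    stopifnot(!is.null(alphas))
    factory <- problems
    problems <- lapply(alphas, factory)
  }
  stopifnot(length(problems) >= 1)
  sols <- vector("list", length(problems))
  guess <- NULL
  for (i in seq_along(problems)) {
    sols[[i]] <- solve_usooc(problems[[i]], N = N,
                             guess = if (warm_start) guess else NULL,
                             control = control)
    if (sols[[i]]$status != "converged" && warm_start && !is.null(guess)) {
      # a warm start from a neighboring instance can sit in the wrong basin
      # (e.g. a marginal-stiffness hold); retry from the model's cold start
      retry <- solve_usooc(problems[[i]], N = N, control = control)
      if (retry$status == "converged" ||
          retry$feasibility < sols[[i]]$feasibility) {
        sols[[i]] <- retry
      }
    }
    if (sols[[i]]$status != "converged" && !is.null(fallback_factory) &&
        !is.null(alphas)) {
      # last resort: solve a simpler related instance and warm-start from it
      simple <- solve_usooc(fallback_factory(alphas[i]), N = N,
                            control = control)
      if (simple$status == "converged") {
        retry <- solve_usooc(problems[[i]], N = N, guess = simple,
                             control = control)
        if (retry$status == "converged" ||
            retry$feasibility < sols[[i]]$feasibility) {
          sols[[i]] <- retry
        }
      }
    }
    if (i == 1 && sols[[1]]$status != "converged") {
      stop("first continuation instance did not converge (status: ",
           sols[[1]]$status, "); provide a better initial instance",
           call. = FALSE)
    }
    if (sols[[i]]$status == "converged") guess <- sols[[i]]
  }
  summary <- tibble::tibble(
    instance = seq_along(sols),
    alpha = if (is.null(alphas)) NA_real_ else alphas,
    cost = vapply(sols, function(s) s$cost, numeric(1)),
    status = vapply(sols, function(s) s$status, character(1)),
    iterations = vapply(sols, function(s) s$iterations, numeric(1))
  )
  attr(sols, "summary") <- summary
  sols
}
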