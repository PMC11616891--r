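# Packed storage for symmetric / lower-triangular matrices.
# P and P2 travel through the augmented state as lower-triangular packed
# vectors of length n(n+1)/2, matching the counted augmented dimension.

#' Pack the lower triangle of a square matrix column-wise
#' @param M square matrix
#' @return numeric vector of length `n(n+1)/2`
#' @keywords internal
#' @noRd
ltri_pack <- function(M) {
  M[lower.tri(M, diag = TRUE)]
}

#' Unpack a lower-triangular packed vector
#'
#' @param v packed vector
#' @param n matrix order
#' @param symmetric if `TRUE`, mirror the lower triangle into the upper one
#'   (for packed symmetric matrices); otherwise leave the upper triangle zero
#'   (for triangular factors).
#' @keywords internal
#' @noRd
ltri_unpack <- function(v, n, symmetric = FALSE) {
  M <- matrix(0, n, n)
  M[lower.tri(M, diag = TRUE)] <- v
  if (symmetric) {
    M[upper.tri(M)] <- t(M)[upper.tri(M)]
  }
  M
}

# Phi operator of the triangular factor dynamics: for a symmetric M,
# L_dot = L * Phi(L^-1 S L^-T) propagates L with P = L L^T and P_dot = S.
# Phi keeps the strict lower triangle and halves the diagonal.
phi_lower <- function(M) {
  out <- M
  out[upper.tri(out)] <- 0
  diag(out) <- diag(out) / 2
  out
}

# Symmetrize (guards tiny asymmetries from floating-point accumulation).
symm <- function(M) (M + t(M)) / 2

#' Check symmetric positive semidefiniteness
#' @keywords internal
#' @noRd
is_psd <- function(M, tol = 1e-8) {
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-7, check.attributes = FALSE))) {
    return(FALSE)
  }
  ev <- eigen(symm(M), symmetric = TRUE, only.values = TRUE)$values
  all(ev >= -tol * max(1, abs(ev[1])))
}

# Lower Cholesky factor with a positive-definiteness floor: a singular or
# indefinite-by-rounding matrix is floored to M + floor*I before factoring.
chol_lower <- function(M, floor = 0) {
  M <- symm(M)
  if (floor > 0) M <- M + floor * diag(nrow(M))
  out <- tryCatch(t(chol(M)), error = function(e) NULL)
  if (is.null(out)) {
    stop("matrix is not positive definite (after flooring); ",
         "cannot form its triangular factor", call. = FALSE)
  }
  out
}

# Moore-Penrose pseudo-inverse of a PSD matrix (eigenvalue thresholding).
pinv_psd <- function(M, tol = 1e-12) {
  eg <- eigen(symm(M), symmetric = TRUE)
  keep <- eg$values > tol * max(eg$values, 1)
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  eg$vectors[, keep, drop = FALSE] %*%
    ((1 / eg$values[keep]) * t(eg$vectors[, keep, drop = FALSE]))
}

# Deterministic probe points in [-1, 1]^k without touching the global RNG
# (golden-ratio lattice). Used by numerical structure checks.
probe_points <- function(k, n_points) {
  phi <- (sqrt(5) - 1) / 2
  idx <- outer(seq_len(n_points), seq_len(k), function(i, j) (i * phi^j) %% 1)
  2 * idx - 1
}

# Dense central-difference Hessian of a scalar function (used only for the
# non-quadratic cost extras, e.g. the arm's endpoint-variance term).
fd_hess <- function(fun, x0) {
  k <- length(x0)
  H <- matrix(0, k, k)
  hstep <- 1e-4 * (1 + abs(x0))
  f0 <- fun(x0)
  fp <- numeric(k); fm <- numeric(k)
  for (i in seq_len(k)) {
    xp <- x0; xp[i] <- xp[i] + hstep[i]; fp[i] <- fun(xp)
    xm <- x0; xm[i] <- xm[i] - hstep[i]; fm[i] <- fun(xm)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / hstep[i]^2
  }
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        xpp <- x0; xpp[i] <- xpp[i] + hstep[i]; xpp[j] <- xpp[j] + hstep[j]
        xmm <- x0; xmm[i] <- xmm[i] - hstep[i]; xmm[j] <- xmm[j] - hstep[j]
        v <- (fun(xpp) - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + fun(xmm)) /
          (2 * hstep[i] * hstep[j])
        H[i, j] <- v; H[j, i] <- v
      }
    }
  }
  H
}

# Column-wise maximum absolute value of a sparse dgCMatrix (= row max for the
# symmetric KKT systems this equilibrates).
col_abs_max <- function(K) {
  K <- methods::as(K, "CsparseMatrix")
  nc <- ncol(K)
  out <- numeric(nc)
  px <- abs(K@x)
  pp <- K@p
  for (j in seq_len(nc)) {
    if (pp[j + 1] > pp[j]) out[j] <- max(px[(pp[j] + 1):pp[j + 1]])
  }
  out
}

# Trapezoidal quadrature weights on a (possibly non-uniform) grid.
trapezoid_weights <- function(times) {
  N <- length(times)
  h <- diff(times)
  w <- numeric(N)
  w[1] <- h[1] / 2
  w[N] <- h[N - 1] / 2
  if (N > 2) w[2:(N - 1)] <- (h[-1] + h[-(N - 1)]) / 2
  w
}
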