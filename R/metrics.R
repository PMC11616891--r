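#' Chebyshev-extrema probability grid
#'
#' Disturbance probabilities taken from the extrema of the Chebyshev
#' polynomial of the given order, mapped to `[0, 1]`:
#' `(1 - cos(k pi / order)) / 2`, `k = 0..order`. The grid samples the edges
#' of the probability range densely, where the stiffness-uncertainty
#' relationship is steepest.
#'
#' @param order polynomial order (>= 1); the grid has `order + 1` nodes.
#' @return increasing vector of probabilities with exact endpoints 0 and 1.
#' @examples
#' chebyshev_alpha_grid(2)  # 0, 0.5, 1
#' @export
chebyshev_alpha_grid <- function(order) {
  stopifnot(order >= 1)
  (1 - cos(seq(0, order) * pi / order)) / 2
}

#' Co-contraction and coactivation of an antagonist pair
#'
#' Co-contraction is the sum of the two antagonist activation traces (it
#' scales the joint stiffness under activation-scaled viscoelastic muscles);
#' coactivation is their pointwise minimum (the shared component producing no
#' net torque).
#'
#' @param u1,u2 equal-length nonnegative activation traces.
#' @return `cocontraction()` returns `u1 + u2`; `coactivation()` returns
#'   `pmin(u1, u2)`.
#' @export
cocontraction <- function(u1, u2) {
  check_activations(u1, u2)
  u1 + u2
}

#' @rdname cocontraction
#' @export
coactivation <- function(u1, u2) {
  check_activations(u1, u2)
  pmin(u1, u2)
}

check_activations <- function(u1, u2) {
  if (length(u1) != length(u2)) {
    stop("activation traces must have equal length", call. = FALSE)
  }
  if (any(u1 < 0) || any(u2 < 0)) {
    stop("activations must be nonnegative", call. = FALSE)
  }
  invisible(TRUE)
}

time_average <- function(x, times) {
  sum(diff(times) * (utils::head(x, -1) + utils::tail(x, -1)) / 2) /
    (max(times) - min(times))
}

require_converged <- function(sol) {
  if (!inherits(sol, "usooc_solution")) {
    stop("a usooc_solution is required", call. = FALSE)
  }
  if (sol$status != "converged") {
    stop("solution did not converge (status: ", sol$status, ")", call. = FALSE)
  }
  invisible(sol)
}

#' Time-averaged stiffness of a solution
#'
#' Evaluates the model's joint-stiffness summary along the optimal solution
#' (for the bilinear stabilization model the stiffness control itself, for
#' single-joint muscle models `k_s (u1 + u2)`, for the planar arm the trace
#' of the joint stiffness matrix) and averages it over the horizon by
#' trapezoidal quadrature.
#'
#' @param sol a converged `usooc_solution` whose problem defines a
#'   `metrics$stiffness` summary.
#' @return scalar time-averaged stiffness.
#' @export
mean_stiffness <- function(sol) {
  require_converged(sol)
  met <- sol$problem$metrics
  if (is.null(met$stiffness)) stop("model defines no stiffness summary", call. = FALSE)
  M <- sol$Z[sol$aug$layout$idx_m, , drop = FALSE]
  time_average(met$stiffness(sol$U, M), sol$times)
}

#' Per-pair antagonist summaries of a solution
#'
#' @param sol a converged `usooc_solution` whose model declares antagonist
#'   pairs over its activation traces.
#' @return tibble with columns `t`, `pair`, `cocontraction`, `coactivation`.
#' @export
antagonist_summary <- function(sol) {
  require_converged(sol)
  met <- sol$problem$metrics
  if (is.null(met$pairs)) stop("model declares no antagonist pairs", call. = FALSE)
  M <- sol$Z[sol$aug$layout$idx_m, , drop = FALSE]
  acts <- met$activations(sol$U, M)
  purrr::map_dfr(seq_along(met$pairs), function(i) {
    pr <- met$pairs[[i]]
    tibble::tibble(
      t = sol$times, pair = i,
      cocontraction = cocontraction(acts[pr[1], ], acts[pr[2], ]),
      coactivation = coactivation(acts[pr[1], ], acts[pr[2], ])
    )
  })
}

#' Sweep the disturbance probability and summarize impedance measures
#'
#' Solves a family of problems over a probability grid by warm-started
#' continuation and summarizes each converged solution: time-averaged
#' stiffness, co-contraction, coactivation and net actuation, together with
#' the task-uncertainty measure `alpha (1 - alpha)`.
#'
#' @param factory `function(alpha)` returning a `usooc_problem`.
#' @param alphas probability grid (e.g. [chebyshev_alpha_grid()]).
#' @param N collocation nodes per instance.
#' @param control solver options.
#' @param fallback_factory optional simpler-instance factory for failed
#'   nodes (see [continuation_solve()]).
#' @return a tibble of class `usooc_sweep` (one row per probability) with the
#'   solutions stored in the `solutions` attribute. Unconverged nodes carry
#'   `NA` summaries and are flagged in `status`.
#' @export
sweep_alpha <- function(factory, alphas, N = NULL, control = list(),
                        fallback_factory = NULL) {
  sols <- continuation_solve(factory, alphas = alphas, N = N, control = control,
                             fallback_factory = fallback_factory)
  rows <- purrr::map_dfr(seq_along(sols), function(i) {
    sol <- sols[[i]]
    conv <- sol$status == "converged"
    met <- sol$problem$metrics
    M <- sol$Z[sol$aug$layout$idx_m, , drop = FALSE]
    acts <- if (conv && !is.null(met$activations)) met$activations(sol$U, M) else NULL
    coco <- coact <- NA_real_
    if (conv && !is.null(met$pairs)) {
      coco <- mean(vapply(met$pairs, function(pr) {
        time_average(cocontraction(acts[pr[1], ], acts[pr[2], ]), sol$times)
      }, numeric(1)))
      coact <- mean(vapply(met$pairs, function(pr) {
        time_average(coactivation(acts[pr[1], ], acts[pr[2], ]), sol$times)
      }, numeric(1)))
    }
    tibble::tibble(
      alpha = alphas[i],
      uncertainty = alphas[i] * (1 - alphas[i]),
      mean_stiffness = if (conv) mean_stiffness(sol) else NA_real_,
      mean_cocontraction = coco,
      mean_coactivation = coact,
      mean_net = if (conv && !is.null(met$net)) {
        time_average(met$net(sol$U, M), sol$times)
      } else NA_real_,
      cost = sol$cost,
      status = sol$status,
      iterations = sol$iterations
    )
  })
  class(rows) <- c("usooc_sweep", class(rows))
  attr(rows, "solutions") <- sols
  rows
}

#' Logarithmic fit of the uncertainty-stiffness relationship
#'
#' Least-squares fit of `y = a log(x + c) + b` with `c > 0` (profiled over
#' `c`, linear in `a, b`), describing the characteristic steep rise of
#' optimal stiffness at low task uncertainty followed by a gentler increase.
#' The fit is compared against the best affine fit; when the logarithmic
#' model offers no residual advantage this is flagged.
#'
#' @param x nonnegative predictor (task uncertainty `alpha (1 - alpha)`).
#' @param y response (mean stiffness).
#' @return object of class `usooc_logfit`: `coefficients` (a, b, c),
#'   `residual_norm`, `affine_residual_norm`, `log_advantage`, and the data.
#' @export
log_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("at least 4 points are required", call. = FALSE)
  if (any(x < 0)) stop("x must be nonnegative", call. = FALSE)
  if (stats::sd(y) == 0) stop("y is constant: nothing to fit", call. = FALSE)
  rss_c <- function(logc) {
    fit <- stats::lm(y ~ log(x + exp(logc)))
    sum(stats::residuals(fit)^2)
  }
  span <- log(c(max(min(x[x > 0], 1e-6) * 1e-3, 1e-9), max(x) * 10 + 1))
  opt <- stats::optimize(rss_c, span, tol = 1e-12)
  cc <- exp(opt$minimum)
  fit <- stats::lm(y ~ log(x + cc))
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  aff <- stats::lm(y ~ x)
  res_log <- sqrt(sum(stats::residuals(fit)^2))
  res_aff <- sqrt(sum(stats::residuals(aff)^2))
  structure(list(
    coefficients = c(a = a, b = b, c = cc),
    residual_norm = res_log,
    affine_residual_norm = res_aff,
    log_advantage = res_log < 0.95 * res_aff,
    fitted = a * log(x + cc) + b,
    data = tibble::tibble(x = x, y = y)
  ), class = "usooc_logfit")
}

#' @export
print.usooc_logfit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<usooc_logfit> y = %.4g * log(x + %.4g) + %.4g\n",
              co["a"], co["c"], co["b"]))
  cat("  residual norm:", signif(x$residual_norm, 4),
      "| affine residual:", signif(x$affine_residual_norm, 4),
      if (!x$log_advantage) "(no log advantage)" else "", "\n")
  invisible(x)
}

#' Co-contraction index over the pre-disturbance window
#'
#' Time-normalized integral of the summed antagonist activations over the
#' 170-ms window from 150 ms before to 20 ms after the disturbance onset —
#' the anticipatory, pre-reflex epoch:
#' `CI = (1 / 0.17) * int_{t0 - 0.15}^{t0 + 0.02} (uF + uE) dt`
#' (trapezoidal quadrature on the trace grid).
#'
#' @param uF,uE flexor and extensor traces on `times`.
#' @param times trace time grid (s).
#' @param t0 disturbance-onset time (s).
#' @return scalar co-contraction index.
#' @export
ci_index <- function(uF, uE, times, t0) {
  lo <- t0 - 0.15; hi <- t0 + 0.02
  if (lo < min(times) - 1e-9 || hi > max(times) + 1e-9) {
    stop("the window [t0 - 0.15, t0 + 0.02] is not covered by the traces",
         call. = FALSE)
  }
  grid <- seq(lo, hi, length.out = 101)
  s <- stats::approx(times, uF + uE, xout = grid)$y
  sum(diff(grid) * (utils::head(s, -1) + utils::tail(s, -1)) / 2) / 0.17
}

#' Normalized co-contraction index
#'
#' Co-contraction index divided by the movement's peak deceleration,
#' mitigating the scaling of muscle activity with movement vigor.
#'
#' @param ci co-contraction index (see [ci_index()]).
#' @param peak_deceleration peak deceleration of the movement (> 0).
#' @return `ci / peak_deceleration`.
#' @export
nci_index <- function(ci, peak_deceleration) {
  if (!is.numeric(peak_deceleration) || peak_deceleration <= 0) {
    stop("peak_deceleration must be positive", call. = FALSE)
  }
  ci / peak_deceleration
}
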