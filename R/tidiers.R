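# broom-style tidiers and ggplot2 autoplot methods

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an optimal-control solution
#'
#' One row per grid node with the controls, the mean-state components, the
#' covariance diagonal and the model's stiffness summary.
#'
#' @param x a `usooc_solution`.
#' @param ... unused.
#' @return a tibble with columns `t`, `u_<j>`, `m_<i>`, `P_<i>_<i>` and
#'   (when the model defines one) `stiffness`.
#' @method tidy usooc_solution
#' @export
tidy.usooc_solution <- function(x, ...) {
  n <- x$problem$n
  M <- x$Z[x$aug$layout$idx_m, , drop = FALSE]
  out <- tibble::tibble(t = x$times)
  for (j in seq_len(x$problem$m)) out[[paste0("u_", j)]] <- x$U[j, ]
  for (i in seq_len(n)) out[[paste0("m_", i)]] <- M[i, ]
  Pd <- vapply(seq_along(x$times), function(k) diag(x$aug$unpack(x$Z[, k])$P),
               numeric(n))
  Pd <- matrix(Pd, n, length(x$times))
  for (i in seq_len(n)) out[[paste0("P_", i, "_", i)]] <- Pd[i, ]
  met <- x$problem$metrics
  if (!is.null(met$stiffness)) out$stiffness <- met$stiffness(x$U, M)
  out
}

#' One-row summary of an optimal-control solution
#'
#' @param x a `usooc_solution`.
#' @param ... unused.
#' @return tibble with `cost`, `status`, `iterations`, `feasibility`,
#'   `optimality`, `nodes`.
#' @method glance usooc_solution
#' @export
glance.usooc_solution <- function(x, ...) {
  tibble::tibble(
    cost = x$cost, status = x$status, iterations = x$iterations,
    feasibility = x$feasibility, optimality = x$optimality,
    nodes = length(x$times)
  )
}

#' @method tidy usooc_logfit
#' @export
tidy.usooc_logfit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @method glance usooc_logfit
#' @export
glance.usooc_logfit <- function(x, ...) {
  tibble::tibble(residual_norm = x$residual_norm,
                 affine_residual_norm = x$affine_residual_norm,
                 log_advantage = x$log_advantage)
}

#' Plot the control and mean-state trajectories of a solution
#'
#' @param object a `usooc_solution`.
#' @param ... unused.
#' @return a ggplot object (controls and mean states, faceted by variable).
#' @method autoplot usooc_solution
#' @export
autoplot.usooc_solution <- function(object, ...) {
  td <- tidy(object)
  long <- tidyr::pivot_longer(td, -"t", names_to = "variable",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = object$problem$name) +
    ggplot2::theme_minimal()
}

#' Plot impedance summaries against the disturbance probability
#'
#' @param object a `usooc_sweep` from [sweep_alpha()].
#' @param ... unused.
#' @return a ggplot object of the mean stiffness, co-contraction and
#'   coactivation against the probability.
#' @method autoplot usooc_sweep
#' @export
autoplot.usooc_sweep <- function(object, ...) {
  keep <- intersect(c("mean_stiffness", "mean_cocontraction",
                      "mean_coactivation", "mean_net"), names(object))
  long <- tidyr::pivot_longer(object, dplyr::all_of(keep),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$alpha, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "disturbance probability", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot usooc_logfit
#' @export
autoplot.usooc_logfit <- function(object, ...) {
  dd <- object$data
  dd$fitted <- object$fitted
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(x = "task uncertainty", y = "mean stiffness") +
    ggplot2::theme_minimal()
}

#' Tidy a Monte-Carlo ensemble into long format
#'
#' @param x a `usooc_ensemble`.
#' @param ... unused.
#' @return tibble with columns `trial`, `t`, one column per state component
#'   and the drawn parameter values.
#' @method tidy usooc_ensemble
#' @export
tidy.usooc_ensemble <- function(x, ...) {
  n <- dim(x$states)[1]; N <- dim(x$states)[2]; K <- dim(x$states)[3]
  out <- tibble::tibble(
    trial = rep(seq_len(K), each = N),
    t = rep(x$times, K)
  )
  for (i in seq_len(n)) out[[paste0("x_", i)]] <- as.numeric(x$states[i, , ])
  for (j in seq_len(nrow(x$xi))) {
    out[[paste0("xi_", j)]] <- rep(x$xi[j, ], each = N)
  }
  out
}
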