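#' Build a problem from a configuration list or YAML file
#'
#' Configuration schema (version 1): a `model` preset (`toy`, `pendulum`,
#' `arm` or `wrist`), the disturbance probability `alpha`, optional
#' model-parameter overrides under `params`, solver settings under `solver`
#' (`nodes`, `feas_tol`, `opt_tol`, `maxit`), and Monte-Carlo settings under
#' `monte_carlo` (`trials`, `dt`, `seed`). All omitted values fall back to the
#' model's documented defaults.
#'
#' @param config path to a YAML file or an already-parsed list.
#' @return list with elements `problem` (a validated `usooc_problem`),
#'   `solver`, `monte_carlo` and the `resolved` configuration (including the
#'   package version and a hash, written next to outputs by the command-line
#'   interface).
#' @export
load_problem_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg), !is.null(cfg$model))
  model <- match.arg(cfg$model, c("toy", "pendulum", "arm", "wrist"))
  params <- cfg$params %||% list()
  if (!is.null(cfg$alpha)) params$alpha <- cfg$alpha
  if (is.null(params$alpha)) stop("alpha (or params$alpha) is required", call. = FALSE)
  factory <- switch(model,
    toy = make_toy_problem,
    pendulum = make_pendulum_problem,
    arm = make_arm_problem,
    wrist = make_wrist_problem
  )
  problem <- do.call(factory, params)
  solver <- utils::modifyList(
    list(nodes = problem$default_N, feas_tol = 1e-8, opt_tol = 1e-6,
         maxit = 3000),
    cfg$solver %||% list()
  )
  mc <- utils::modifyList(list(trials = 1000, dt = NULL, seed = 1),
                          cfg$monte_carlo %||% list())
  resolved <- list(schema_version = 1, model = model, params = params,
                   solver = solver, monte_carlo = mc,
                   package_version = as.character(utils::packageVersion("usooc")))
  resolved$config_hash <- rlang::hash(resolved)
  list(problem = problem, solver = solver, monte_carlo = mc,
       resolved = resolved)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a trajectory tibble to CSV or JSON
#'
#' @param traj a tibble (e.g. from [tidy.usooc_solution()] or
#'   [tidy_augmented()]).
#' @param path output file; the extension (`.csv` or `.json`) selects the
#'   format.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(traj, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(traj, path, digits = NA, dataframe = "columns")
  } else {
    utils::write.csv(traj, path, row.names = FALSE)
  }
  invisible(path)
}
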