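#' Arithmetic mini-language for configuration expressions
#'
#' Kernel rates, transition centers, force fields and initial profiles may
#' be given in configuration files as strings in a restricted arithmetic
#' language over the named variables (\code{u} for fields and profiles,
#' \code{u1, u2} for encounter kernels): numeric literals, the named
#' variables, the operators \code{+ - * / ^} and the functions \code{exp,
#' log, sqrt, sin, cos, tan, tanh, abs, pmin, pmax}. Anything else is
#' rejected before evaluation.
#'
#' @param text a single expression string, e.g. \code{"0.75 * (1 - u^2)"}.
#' @param vars character vector of permitted variable names.
#' @return A vectorized function of the variables in \code{vars}.
#' @export
parse_expr_fun <- function(text, vars) {
  if (!is.character(text) || length(text) != 1L)
    ktap_stop("config-type", "expression must be a single string")
  allowed <- c("+", "-", "*", "/", "^", "(", "exp", "log", "sqrt", "sin",
               "cos", "tan", "tanh", "abs", "pmin", "pmax")
  expr <- tryCatch(parse(text = text)[[1L]],
                   error = function(e)
                     ktap_stop("config-expression", "cannot parse %s", text))
  walk <- function(e) {
    if (is.numeric(e)) return(invisible())
    if (is.name(e)) {
      if (!(as.character(e) %in% vars))
        ktap_stop("config-expression",
                  "variable '%s' not permitted (allowed: %s)",
                  as.character(e), paste(vars, collapse = ", "))
      return(invisible())
    }
    if (is.call(e)) {
      fn <- as.character(e[[1L]])
      if (!(fn %in% allowed))
        ktap_stop("config-expression", "call to '%s' not permitted", fn)
      for (arg in as.list(e)[-1L]) walk(arg)
      return(invisible())
    }
    ktap_stop("config-expression", "unsupported construct in %s", text)
  }
  walk(expr)
  fenv <- new.env(parent = emptyenv())
  for (fn in setdiff(allowed, "(")) assign(fn, get(fn, baseenv()), fenv)
  assign("(", get("(", baseenv()), fenv)
  function(...) {
    args <- list(...)
    names(args) <- vars[seq_along(args)]
    eval(expr, args, fenv)
  }
}

.num_or_expr <- function(x, vars, path) {
  if (is.numeric(x) && length(x) == 1L) return(x)
  if (is.character(x)) return(parse_expr_fun(x, vars))
  ktap_stop("config-type", "%s must be a number or expression string", path)
}

.check_keys <- function(tree, required, optional, path) {
  if (!is.list(tree))
    ktap_stop("config-type", "%s must be a mapping", path)
  unknown <- setdiff(names(tree), c(required, optional))
  if (length(unknown))
    ktap_stop("config-unknown-key", "unknown key %s.%s", path, unknown[1L])
  missing <- setdiff(required, names(tree))
  if (length(missing))
    ktap_stop("config-missing-key", "missing key %s.%s", path, missing[1L])
  invisible(TRUE)
}

#' Load a model + run configuration file
#'
#' Reads a YAML document with sections \code{grid} (u_min, u_max, M >= 4),
#' \code{velocities} (list of values), \code{kernels} (iota, A, pi),
#' \code{force}, \code{thermostat}, \code{initial} (expr, optional mass)
#' and \code{run} (integration settings; defaults applied), plus an
#' optional \code{output} (prefix). Rates, centers, the force and the
#' initial profile accept the expression language of
#' \code{\link{parse_expr_fun}}. Unknown keys anywhere are rejected, each
#' failure carrying a distinct machine-greppable class naming the
#' offending path.
#'
#' @param path file path.
#' @return A list with \code{model} (a \code{"ktap_model"}), \code{f0},
#'   \code{run} (a \code{\link{run_config}}), \code{output} (prefix or
#'   NULL) and \code{tree} (the normalized configuration with defaults
#'   applied, suitable for re-serialization).
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    ktap_stop("io-error", "config file not found: %s", path)
  tree <- yaml::read_yaml(path)
  .check_keys(tree, c("grid", "velocities", "kernels", "initial", "run"),
              c("force", "thermostat", "output"), "config")
  .check_keys(tree$grid, c("u_min", "u_max", "M"), character(), "grid")
  gM <- tree$grid$M
  if (!is.numeric(gM) || gM < 4)
    ktap_stop("config-range", "grid.M must be an integer >= 4")
  grid <- activity_grid(tree$grid$u_min, tree$grid$u_max, gM)
  if (!is.numeric(unlist(tree$velocities)))
    ktap_stop("config-type", "velocities must be numeric")
  vel <- velocity_set(unlist(tree$velocities))
  .check_keys(tree$kernels, c("iota", "A", "pi"), character(), "kernels")
  iota <- .num_or_expr(tree$kernels$iota, c("u1", "u2"), "kernels.iota")
  pi_rate <- .num_or_expr(tree$kernels$pi, c("u1", "u2"), "kernels.pi")
  A <- tree$kernels$A
  .check_keys(A, "type", c("sigma", "center"), "kernels.A")
  transition <- switch(A$type,
    uniform = transition_uniform(grid),
    gaussian = {
      if (is.null(A$sigma))
        ktap_stop("config-missing-key", "missing key kernels.A.sigma")
      ctr <- if (is.null(A$center)) 0
             else .num_or_expr(A$center, c("u1", "u2"), "kernels.A.center")
      transition_gaussian(grid, center = ctr, sigma = A$sigma)
    },
    ktap_stop("config-range",
              "kernels.A.type must be 'uniform' or 'gaussian'")
  )
  kern <- interaction_kernels(grid, vel$n, iota = iota,
                              transition = transition, pi_rate = pi_rate)
  force <- if (is.null(tree$force)) 0
           else .num_or_expr(tree$force, "u", "force")
  thermostat <- isTRUE(tree$thermostat)
  model <- kinetic_model(grid, vel, kern, force = force,
                         thermostat = thermostat)
  .check_keys(tree$initial, "expr", "mass", "initial")
  f0_fun <- parse_expr_fun(tree$initial$expr, "u")
  f0 <- initial_state(model, function(u) f0_fun(u) + 0 * u,
                      mass = tree$initial$mass)
  run_defaults <- list(t_end = NULL, dt_max = 0.1, cfl = 0.9,
                       record_every = 5L, blowup_mass = 1e4, safety = 0.5,
                       tol_neg = 1e-10, seed = 1L)
  .check_keys(tree$run, "t_end", setdiff(names(run_defaults), "t_end"),
              "run")
  rc <- utils::modifyList(run_defaults, tree$run)
  if (!is.numeric(rc$cfl) || rc$cfl <= 0 || rc$cfl > 1)
    ktap_stop("config-range", "run.cfl must lie in (0, 1]")
  cfg <- run_config(t_end = rc$t_end, dt_max = rc$dt_max, cfl = rc$cfl,
                    record_every = rc$record_every,
                    blowup_mass = rc$blowup_mass, safety = rc$safety,
                    tol_neg = rc$tol_neg, seed = rc$seed)
  output <- NULL
  if (!is.null(tree$output)) {
    .check_keys(tree$output, "prefix", character(), "output")
    output <- tree$output$prefix
  }
  norm <- tree
  norm$force <- if (is.null(tree$force)) 0 else tree$force
  norm$thermostat <- thermostat
  norm$run <- rc
  list(model = model, f0 = f0, run = cfg, output = output, tree = norm)
}

#' Serialize a (normalized) configuration tree back to YAML
#'
#' @param tree the \code{tree} element returned by \code{\link{load_config}}.
#' @param path destination file.
#' @export
write_config <- function(tree, path) {
  yaml::write_yaml(tree, path)
  invisible(path)
}

.fmt17 <- function(x) sprintf("%.17g", x)

#' Write run results to disk
#'
#' Writes three files sharing a prefix: \code{<prefix>_moments.csv} (the
#' moment series, floats at 17 significant digits so repeated identical
#' runs produce byte-identical files), \code{<prefix>_final.csv} (the
#' final n x M state, preceded by a one-line header with the grid
#' metadata) and \code{<prefix>_summary.json} (status, blow-up estimate,
#' invariant diagnostics including the transition-density zero-mean check
#' and the constant-kernel flags, configuration echo, seed and package
#' version).
#'
#' @param result a \code{"ktap_run"}.
#' @param prefix path prefix for the three output files.
#' @param config_echo optional configuration tree to embed in the summary.
#' @return Invisibly, the vector of file paths written.
#' @export
write_results <- function(result, prefix, config_echo = NULL) {
  stopifnot(inherits(result, "ktap_run"))
  dir <- dirname(prefix)
  if (!dir.exists(dir))
    ktap_stop("io-error", "output directory does not exist: %s", dir)
  paths <- paste0(prefix, c("_moments.csv", "_final.csv", "_summary.json"))
  m <- result$moments
  mm <- as.data.frame(lapply(m, .fmt17), stringsAsFactors = FALSE)
  names(mm) <- names(m)
  write.csv(mm, paths[1L], row.names = FALSE, quote = FALSE)
  g <- result$model$grid
  hdr <- sprintf("# n=%d M=%d u_min=%.17g u_max=%.17g du=%.17g time=%.17g",
                 result$model$velocities$n, g$M, g$u_min, g$u_max, g$du,
                 result$final_time)
  rows <- apply(result$final, 1L, function(r)
    paste(.fmt17(r), collapse = ","))
  writeLines(c(hdr, rows), paths[2L])
  kern <- result$model$kernels
  zm <- transition_mean(kernel_transition(kern, 1L, 1L))
  summary <- list(
    status = result$status,
    final_time = result$final_time,
    n_steps = result$n_steps,
    blowup_time_estimate = if (is.na(result$blowup_time_estimate)) NULL
                           else result$blowup_time_estimate,
    min_f_observed = result$min_f_observed,
    diagnostics = list(
      mass_initial = m$mu[1L],
      mass_final = m$mu[nrow(m)],
      E_1_1_final = m$E_1_1[nrow(m)],
      transition_zero_mean_error = max(abs(zm)),
      iota_constant = kern$iota_const,
      pi_constant = kern$pi_const,
      force_constant = result$model$force_const
    ),
    seed = result$config$seed,
    config = config_echo,
    package_version = as.character(utils::packageVersion("ktap"))
  )
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"), paths[3L])
  invisible(paths)
}
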