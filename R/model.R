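#' Assemble a hybrid kinetic model
#'
#' A model couples the activity grid, the discrete velocity set, the
#' interaction kernels, an external field F_i(u) acting on the activity
#' variable, and the thermostat switch. With the field off the dynamics
#' reduce to the interaction-only (equilibrium) framework; with the field on
#' and the thermostat off the activity is transported by the raw field; with
#' the thermostat on, the transport flux is damped by the instantaneous
#' first activation moment E1, giving the controlled framework whose moments
#' obey Riccati equations.
#'
#' @param grid an \code{\link{activity_grid}}.
#' @param velocities a \code{\link{velocity_set}} (or numeric vector).
#' @param kernels a \code{"ktap_kernels"} object built on the same grid and
#'   the same number of velocity classes.
#' @param force external field: a single number, a vectorized function
#'   \code{F(u)}, or a list of length n of either (one per velocity class).
#' @param thermostat logical; include the damping term in the transport
#'   flux.
#' @return An object of class \code{"ktap_model"}.
#' @examples
#' g <- activity_grid(-1, 1, 50)
#' kern <- interaction_kernels(g, n = 1, iota = 1,
#'                             transition = transition_uniform(g))
#' m <- kinetic_model(g, velocity_set(1), kern)
#' @export
kinetic_model <- function(grid, velocities, kernels, force = 0,
                          thermostat = FALSE) {
  stopifnot(inherits(grid, "activity_grid"),
            inherits(kernels, "ktap_kernels"))
  if (!inherits(velocities, "velocity_set"))
    velocities <- velocity_set(velocities)
  n <- velocities$n
  if (kernels$n != n)
    ktap_stop("dimension-mismatch",
              "kernels built for n = %d velocity classes, model has n = %d",
              kernels$n, n)
  if (kernels$grid$M != grid$M)
    ktap_stop("dimension-mismatch",
              "kernels built on M = %d cells, grid has M = %d",
              kernels$grid$M, grid$M)
  ff <- .force_eval(force, n, grid)
  structure(list(
    grid = grid, velocities = velocities, kernels = kernels,
    force = force, F_centers = ff$centers, F_faces = ff$faces,
    force_const = ff$const, force_value = ff$value,
    thermostat = isTRUE(thermostat)
  ), class = "ktap_model")
}

# Evaluate the external field at cell centers (n x M) and faces (n x (M+1)).
.force_eval <- function(force, n, grid) {
  one <- function(f) {
    if (is.numeric(f) && length(f) == 1L) {
      if (!is.finite(f)) ktap_stop("invalid-parameter", "force must be finite")
      list(c = rep(f, grid$M), f = rep(f, grid$M + 1L), const = TRUE,
           value = as.numeric(f))
    } else if (is.function(f)) {
      fc <- f(grid$centers); fa <- f(grid$faces)
      if (length(fc) != grid$M || length(fa) != grid$M + 1L ||
          any(!is.finite(c(fc, fa))))
        ktap_stop("invalid-parameter",
                  "force function must be vectorized and finite on the grid")
      rng <- range(c(fc, fa))
      list(c = fc, f = fa, const = diff(rng) == 0, value = rng[1])
    } else ktap_stop("invalid-parameter",
                     "force must be a number or a function of u")
  }
  specs <- if (is.list(force)) {
    if (length(force) != n)
      ktap_stop("dimension-mismatch",
                "force list must have one entry per velocity class")
    lapply(force, one)
  } else rep(list(one(force)), n)
  list(
    centers = do.call(rbind, lapply(specs, `[[`, "c")),
    faces   = do.call(rbind, lapply(specs, `[[`, "f")),
    const   = all(vapply(specs, `[[`, TRUE, "const")) &&
              length(unique(vapply(specs, `[[`, 0, "value"))) == 1L,
    value   = specs[[1L]]$value
  )
}

#' @export
print.ktap_model <- function(x, ...) {
  cat(sprintf(
    "hybrid kinetic model: n = %d velocity classes, M = %d activity cells on [%g, %g]\n",
    x$velocities$n, x$grid$M, x$grid$u_min, x$grid$u_max))
  cat(sprintf("  force: %s, thermostat: %s\n",
              if (x$force_const) sprintf("constant %g", x$force_value)
              else "u-dependent",
              if (x$thermostat) "on" else "off"))
  print(x$kernels)
  invisible(x)
}

#' Build an initial state on a model's grid
#'
#' @param model a \code{"ktap_model"}.
#' @param f a vectorized function \code{f(u)} applied to every velocity
#'   class, a list of n such functions, or an n x M numeric matrix.
#' @param mass if not \code{NULL}, rescale so the total mass (zeroth moment
#'   mu) equals this value exactly in the discrete sum.
#' @return An n x M matrix of nonnegative cell-center values.
#' @export
initial_state <- function(model, f, mass = NULL) {
  stopifnot(inherits(model, "ktap_model"))
  n <- model$velocities$n; g <- model$grid
  st <- if (is.matrix(f)) {
    if (!all(dim(f) == c(n, g$M)))
      ktap_stop("dimension-mismatch", "state must be %d x %d", n, g$M)
    f
  } else if (is.function(f)) {
    matrix(rep(f(g$centers), each = n), n, g$M, byrow = FALSE)
  } else if (is.list(f) && length(f) == n) {
    do.call(rbind, lapply(f, function(fi) fi(g$centers)))
  } else ktap_stop("invalid-parameter",
                   "f must be a function, list of functions, or matrix")
  if (any(!is.finite(st)) || min(st) < 0)
    ktap_stop("invalid-parameter",
              "initial state must be finite and nonnegative")
  if (!is.null(mass)) st <- st * (mass / (sum(st) * g$du))
  st
}

#' Canonical test scenarios
#'
#' A small catalogue of fully specified, analytically tractable model +
#' initial-state pairs used throughout the package's tests and validation
#' harness:
#' \describe{
#'   \item{"conservative-uniform"}{one velocity class v = 1 on
#'     \code{[-1, 1]}, iota = 1, pi = 0, no field, uniform transition
#'     density, uniform initial profile f = 0.5 (total mass mu = 1). The
#'     uniform profile is an interaction equilibrium: gain and loss cancel
#'     pointwise and the mass is exactly conserved.}
#'   \item{"proliferative"}{as above but with net birth rate pi = 0.5: the
#'     mass obeys dmu/dt = iota * pi * mu^2 and blows up at t = 2.}
#'   \item{"thermostated"}{as "conservative-uniform" but with constant field
#'     F = 1 and the thermostat on; initial profile proportional to
#'     1 - u^2 (vanishing at the boundary, even, so E1(0) = 0), normalized
#'     to mu = 1. This is the configuration in which the first activation
#'     moment is compared against its Riccati ODE.}
#' }
#'
#' @param name one of \code{"conservative-uniform"}, \code{"proliferative"},
#'   \code{"thermostated"}.
#' @param M number of activity cells (the catalogue default is 100).
#' @return A list with elements \code{model} (a \code{"ktap_model"}) and
#'   \code{f0} (the 1 x M initial state).
#' @export
ktap_scenario <- function(name, M = 100L) {
  valid <- c("conservative-uniform", "proliferative", "thermostated")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    ktap_stop("unknown-scenario",
              "unknown scenario %s; valid names: %s",
              deparse(substitute(name)), paste(valid, collapse = ", "))
  g <- activity_grid(-1, 1, M)
  v <- velocity_set(1)
  pi_rate <- if (name == "proliferative") 0.5 else 0
  kern <- interaction_kernels(g, n = 1, iota = 1,
                              transition = transition_uniform(g),
                              pi_rate = pi_rate)
  if (name == "thermostated") {
    model <- kinetic_model(g, v, kern, force = 1, thermostat = TRUE)
    f0 <- initial_state(model, function(u) 0.75 * (1 - u^2), mass = 1)
  } else {
    model <- kinetic_model(g, v, kern, force = 0, thermostat = FALSE)
    f0 <- initial_state(model, function(u) rep(0.5, length(u)))
  }
  list(model = model, f0 = f0, name = name)
}
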