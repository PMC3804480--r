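#' Uniform finite-volume grid on the activity interval
#'
#' The continuous activity variable u lives on a bounded interval
#' \code{[u_min, u_max]} discretized into \code{M} cells of equal width
#' \code{du}. Distributions are represented by their cell-center values and
#' all integrals over u are midpoint (cell-average) sums, so the grid object
#' carries both cell centers and cell faces (the latter are used by the
#' upwind transport flux).
#'
#' @param u_min,u_max interval endpoints, \code{u_min < u_max}. The default
#'   symmetric interval \code{[-1, 1]} supports zero-mean transition
#'   densities, the setting in which the moment ODE layer is exact.
#' @param M number of cells (positive integer).
#' @return An object of class \code{"activity_grid"}: a list with fields
#'   \code{u_min}, \code{u_max}, \code{M}, \code{du}, \code{centers}
#'   (length M) and \code{faces} (length M + 1).
#' @examples
#' g <- activity_grid(-1, 1, 10)
#' sum(rep(0.5, g$M) * g$du) # midpoint integral of the uniform density
#' @export
activity_grid <- function(u_min = -1, u_max = 1, M = 100L) {
  if (!is.numeric(u_min) || !is.numeric(u_max) ||
      length(u_min) != 1L || length(u_max) != 1L ||
      !is.finite(u_min) || !is.finite(u_max) || u_min >= u_max)
    ktap_stop("invalid-grid", "need finite u_min < u_max (got %s, %s)",
              format(u_min), format(u_max))
  if (!is.numeric(M) || length(M) != 1L || !is.finite(M) || M < 1 ||
      M != round(M))
    ktap_stop("invalid-grid", "M must be a positive integer (got %s)",
              format(M))
  M <- as.integer(M)
  du <- (u_max - u_min) / M
  structure(list(
    u_min   = u_min,
    u_max   = u_max,
    M       = M,
    du      = du,
    centers = u_min + (seq_len(M) - 0.5) * du,
    faces   = u_min + (0:M) * du
  ), class = "activity_grid")
}

#' @export
print.activity_grid <- function(x, ...) {
  cat(sprintf("activity grid on [%g, %g], M = %d cells, du = %g\n",
              x$u_min, x$u_max, x$M, x$du))
  invisible(x)
}

#' Discrete velocity set
#'
#' In the hybrid representation the velocity variable attains finitely many
#' values v_1, ..., v_n and the distribution function is the finite family
#' f_i(t, u), one component per velocity. Velocities enter the moment
#' functionals only through scalar powers v_i^p, so they are stored as
#' scalars.
#'
#' @param values numeric vector of finite velocity values (n >= 1).
#'   Duplicated values are permitted but trigger a warning.
#' @return An object of class \code{"velocity_set"} with fields
#'   \code{values} and \code{n}.
#' @export
velocity_set <- function(values) {
  if (!is.numeric(values) || length(values) < 1L || any(!is.finite(values)))
    ktap_stop("invalid-velocities", "need at least one finite velocity value")
  values <- as.numeric(values)
  if (anyDuplicated(values))
    ktap_warn("duplicate-velocities",
              "velocity set contains duplicated values")
  structure(list(values = values, n = length(values)),
            class = "velocity_set")
}

#' @export
print.velocity_set <- function(x, ...) {
  cat(sprintf("velocity set, n = %d: %s\n", x$n,
              paste(format(x$values), collapse = ", ")))
  invisible(x)
}
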