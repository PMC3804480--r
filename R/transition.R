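#' Transition probability densities over the outgoing activity
#'
#' After a binary encounter between a candidate cell with activity u1 and a
#' field cell with activity u2, the candidate acquires an outgoing activity u
#' drawn from the transition probability density A(u1, u2, u). The density is
#' stored discretely on the activity grid and renormalized per incoming pair
#' so that the midpoint sum rule \code{sum(A) * du == 1} holds exactly; this
#' makes the gain/loss mass cancellation of conservative interactions exact
#' at the discrete level.
#'
#' \code{transition_uniform()} builds the flat density with value
#' \code{1/(u_max - u_min)} in every cell, independent of the incoming pair.
#' On a symmetric interval its discrete mean over u is zero, the condition
#' under which the first-activity-moment ODE of the controlled framework is
#' exact.
#'
#' @param grid an \code{\link{activity_grid}}.
#' @return An object of class \code{"ktap_transition"}. Separable densities
#'   (independent of the incoming pair) store a single length-M vector
#'   \code{dens}; pair-dependent densities store an M x M x M array
#'   \code{arr} indexed \code{[k1, k2, k]} plus a flattened matrix used by
#'   the gain contraction.
#' @seealso [transition_gaussian()], [transition_slice()], [transition_mean()]
#' @examples
#' g <- activity_grid(-1, 1, 4)
#' A <- transition_uniform(g)
#' sum(transition_slice(A, 1, 1)) * g$du # exactly 1
#' @export
transition_uniform <- function(grid) {
  stopifnot(inherits(grid, "activity_grid"))
  dens <- rep(1 / (grid$u_max - grid$u_min), grid$M)
  dens <- dens / (sum(dens) * grid$du) # exact discrete normalization
  structure(list(type = "uniform", separable = TRUE, dens = dens,
                 grid = grid),
            class = "ktap_transition")
}

#' Bell-shaped (truncated Gaussian) transition density
#'
#' A smooth alternative to the uniform density: the outgoing activity is
#' concentrated around a center that may depend on the incoming pair.
#' The Gaussian is evaluated at cell centers, truncated to the activity
#' interval and renormalized per incoming pair so the discrete sum rule
#' holds exactly.
#'
#' @param grid an \code{\link{activity_grid}}.
#' @param center either a single number (pair-independent center, giving a
#'   separable density) or a function \code{center(u1, u2)} evaluated at
#'   cell centers of the incoming pair.
#' @param sigma positive spread of the bell. For \code{sigma} much larger
#'   than the interval width the density approaches the uniform one.
#' @return A \code{"ktap_transition"} object; see
#'   \code{\link{transition_uniform}}.
#' @export
transition_gaussian <- function(grid, center = 0, sigma) {
  stopifnot(inherits(grid, "activity_grid"))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    ktap_stop("invalid-parameter", "sigma must be a positive real (got %s)",
              format(sigma))
  u <- grid$centers
  if (is.numeric(center) && length(center) == 1L) {
    if (center < grid$u_min || center > grid$u_max)
      ktap_warn("center-outside-domain",
                "transition center %g lies outside [%g, %g]",
                center, grid$u_min, grid$u_max)
    dens <- .norm_slice(dnorm(u, mean = center, sd = sigma), u, center,
                        grid$du)
    return(structure(list(type = "gaussian", separable = TRUE, dens = dens,
                          center = center, sigma = sigma, grid = grid),
                     class = "ktap_transition"))
  }
  if (!is.function(center))
    ktap_stop("invalid-parameter",
              "center must be a number or a function(u1, u2)")
  M <- grid$M
  cmat <- outer(u, u, center)
  if (any(cmat < grid$u_min | cmat > grid$u_max))
    ktap_warn("center-outside-domain",
              "some transition centers lie outside [%g, %g]",
              grid$u_min, grid$u_max)
  arr <- array(0, dim = c(M, M, M))
  for (k in seq_len(M)) arr[, , k] <- dnorm(u[k], mean = cmat, sd = sigma)
  # renormalize each incoming-pair slice; empty slices collapse onto the
  # cell nearest the requested center
  s <- rowSums(matrix(arr, M * M, M)) * grid$du
  empty <- which(s == 0)
  if (length(empty)) {
    for (idx in empty) {
      k1 <- ((idx - 1L) %% M) + 1L
      k2 <- ((idx - 1L) %/% M) + 1L
      arr[k1, k2, which.min(abs(u - cmat[k1, k2]))] <- 1
    }
    s <- rowSums(matrix(arr, M * M, M)) * grid$du
  }
  arr <- arr / as.vector(s)
  structure(list(type = "gaussian", separable = FALSE, arr = arr,
                 mat = matrix(arr, M * M, M), sigma = sigma, grid = grid),
            class = "ktap_transition")
}

.norm_slice <- function(dens, u, center, du) {
  s <- sum(dens) * du
  if (s == 0) { # fully underflowed bell: all mass to the nearest cell
    dens[which.min(abs(u - center))] <- 1
    s <- sum(dens) * du
  }
  dens / s
}

#' Extract the outgoing-activity density for one incoming pair
#'
#' @param tr a \code{"ktap_transition"}.
#' @param k1,k2 cell indices of the candidate (k1) and field (k2) activity.
#' @return Numeric vector of length M; \code{sum(.) * du} is exactly 1.
#' @export
transition_slice <- function(tr, k1, k2) {
  stopifnot(inherits(tr, "ktap_transition"))
  if (tr$separable) tr$dens else tr$arr[k1, k2, ]
}

#' Discrete mean of the outgoing activity
#'
#' The first moment \code{sum(u * A) * du} of the transition density in its
#' outgoing argument. A zero mean (for every incoming pair) is the validity
#' precondition under which conservative interactions leave the first
#' activity moment untouched, so that the controlled moment ODE layer is an
#' exact description of the kinetic dynamics.
#'
#' @inheritParams transition_slice
#' @return For separable densities a single number, otherwise an M x M
#'   matrix of means indexed by the incoming pair.
#' @export
transition_mean <- function(tr) {
  stopifnot(inherits(tr, "ktap_transition"))
  g <- tr$grid
  if (tr$separable) return(sum(g$centers * tr$dens) * g$du)
  matrix(tr$mat %*% g$centers * g$du, g$M, g$M)
}

# Expand a separable density to the dense M x M x M representation; used by
# the slow contraction path and by tests that compare the two gain routes.
as_dense_transition <- function(tr) {
  stopifnot(inherits(tr, "ktap_transition"))
  if (!tr$separable) return(tr)
  M <- tr$grid$M
  arr <- array(rep(tr$dens, each = M * M), dim = c(M, M, M))
  structure(list(type = tr$type, separable = FALSE, arr = arr,
                 mat = matrix(arr, M * M, M), grid = tr$grid),
            class = "ktap_transition")
}

#' @export
print.ktap_transition <- function(x, ...) {
  cat(sprintf("transition density: %s, %s, M = %d\n", x$type,
              if (x$separable) "pair-independent" else "pair-dependent",
              x$grid$M))
  invisible(x)
}
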