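#' Right-hand-side operators of the controlled kinetic framework
#'
#' The kinetic equation for the family f_i(t, u) reads, per velocity class,
#'
#'   d/dt f_i + d/du ( F_i(u) f_i - T_i ) =
#'       sum_j ( G_ij - L_ij + N_ij ),
#'
#' with the gain G, loss L and nonconservative N interaction operators and,
#' when the thermostat is on, the damping term T_i = u F_i(u) f_i E1 built
#' from the instantaneous first activation moment E1. These functions
#' evaluate each operator on the grid and return an n x M matrix.
#'
#' Gain uses the discrete double integral
#'   G_i(u_k) = sum_j sum_{k1,k2} iota(u_k1,u_k2) A(u_k1,u_k2,u_k)
#'              f_i(u_k1) f_j(u_k2) du^2,
#' evaluated as a bilinear form when the transition density is
#' pair-independent (cost O(n^2 M^2)) and as a dense tensor contraction
#' otherwise; the two routes agree to roundoff.
#'
#' @param f n x M nonnegative state matrix.
#' @param model a \code{"ktap_model"}.
#' @return n x M numeric matrix of operator values at cell centers.
#' @name operators
NULL

check_state <- function(f, model) {
  if (!is.matrix(f) || !all(dim(f) == c(model$velocities$n, model$grid$M)))
    ktap_stop("dimension-mismatch", "state must be an n x M = %d x %d matrix",
              model$velocities$n, model$grid$M)
  if (any(!is.finite(f)))
    ktap_stop("numerical-error", "state contains non-finite values")
  invisible(TRUE)
}

#' @rdname operators
#' @export
gain_term <- function(f, model) {
  check_state(f, model)
  kern <- model$kernels
  n <- kern$n; du <- model$grid$du
  G <- matrix(0, n, model$grid$M)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    iota <- kernel_iota(kern, i, j)
    tr <- kernel_transition(kern, i, j)
    if (tr$separable) {
      s <- as.numeric(f[i, , drop = FALSE] %*% iota %*% f[j, ]) * du^2
      G[i, ] <- G[i, ] + tr$dens * s
    } else {
      w <- iota * tcrossprod(f[i, ], f[j, ]) * du^2
      G[i, ] <- G[i, ] + as.vector(crossprod(tr$mat, as.vector(w)))
    }
  }
  G
}

#' @rdname operators
#' @export
loss_term <- function(f, model) {
  check_state(f, model)
  kern <- model$kernels
  n <- kern$n; du <- model$grid$du
  L <- matrix(0, n, model$grid$M)
  for (i in seq_len(n)) for (j in seq_len(n))
    L[i, ] <- L[i, ] + f[i, ] *
      as.vector(kernel_iota(kern, i, j) %*% f[j, ]) * du
  L
}

#' @rdname operators
#' @export
nonconservative_term <- function(f, model) {
  check_state(f, model)
  kern <- model$kernels
  n <- kern$n; du <- model$grid$du
  N <- matrix(0, n, model$grid$M)
  for (i in seq_len(n)) for (j in seq_len(n))
    N[i, ] <- N[i, ] + f[i, ] *
      as.vector((kernel_iota(kern, i, j) * kernel_pi(kern, i, j)) %*%
                  f[j, ]) * du
  N
}

#' Thermostat (damping) operator
#'
#' The control term T_i(u) = u F_i(u) f_i(u) E1, where E1 is the first
#' activation moment of the current state. The caller supplies E1 so the
#' same state can be probed with frozen or instantaneous moments; inside
#' the time stepper E1 is always recomputed from the stage state.
#'
#' @inheritParams operators
#' @param E1 the first activation moment of \code{f} (see
#'   \code{\link{moment_pq}} with p = q = 1).
#' @return n x M matrix of the damping term at cell centers.
#' @export
thermostat_term <- function(f, model, E1) {
  check_state(f, model)
  u <- model$grid$centers
  model$F_centers * f * rep(u * E1, each = model$velocities$n)
}

#' Transport contribution of the (damped) external field
#'
#' Minus the divergence of the advective flux
#' Phi_i(u) = F_i(u) (1 - u E1 [thermostat]) f_i(u), discretized in
#' conservative finite-volume form with first-order upwind numerical fluxes
#' and zero ghost states (the distribution is taken to vanish outside the
#' activity interval, matching the vanishing-boundary hypothesis of the
#' moment analysis). Total mass then changes only through the physical
#' boundary flux.
#'
#' @inheritParams thermostat_term
#' @return n x M matrix, the transport right-hand-side contribution.
#' @export
transport_term <- function(f, model, E1) {
  check_state(f, model)
  n <- model$velocities$n; M <- model$grid$M
  du <- model$grid$du; uf <- model$grid$faces
  damp <- if (model$thermostat) 1 - uf * E1 else rep(1, M + 1L)
  out <- matrix(0, n, M)
  for (i in seq_len(n)) {
    a <- model$F_faces[i, ] * damp
    if (any(!is.finite(a)))
      ktap_stop("numerical-error", "non-finite advective face speed")
    fl <- ifelse(a >= 0, a * c(0, f[i, ]), a * c(f[i, ], 0))
    out[i, ] <- -(fl[-1L] - fl[-(M + 1L)]) / du
  }
  out
}

#' Full right-hand side of the kinetic equation
#'
#' gain - loss + nonconservative + transport, with the first activation
#' moment entering the thermostat recomputed from the supplied state. With
#' the field off this is the interaction-only framework; with the field on
#' and the thermostat off, the raw forced framework.
#'
#' @inheritParams operators
#' @return n x M matrix d/dt f.
#' @export
kinetic_rhs <- function(f, model) {
  rhs <- gain_term(f, model) - loss_term(f, model) +
    nonconservative_term(f, model)
  if (!(model$force_const && model$force_value == 0)) {
    E1 <- moment_pq(f, model, 1L, 1L)
    rhs <- rhs + transport_term(f, model, E1)
  }
  rhs
}
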