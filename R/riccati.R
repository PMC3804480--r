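#' Parameters of the moment ordinary differential equations
#'
#' Under constant encounter rate iota, constant net birth/death rate pi and
#' constant field F, the first activation moment E1 = E_{1,1} of the
#' controlled kinetic framework obeys the Riccati equation
#'
#'   dE1/dt = F (mu_bar(t) - E1^2) - iota (1 - pi) mu(t) E1,
#'
#' where mu is the total mass and mu_bar the velocity-weighted mass. The
#' general (p, q) moment obeys a companion Riccati equation involving
#' E_{p,q-1} and mu_tilde(t) = sum v_i^p mu_i(t); the printed form of that
#' equation carries the interaction term with the opposite sign to the
#' E1 equation, which cannot be reconciled from the statement alone, so
#' both variants are available through \code{sign_mode} (the default is the
#' sign consistent with the E1 equation, which is the one the kinetic
#' simulation confirms).
#'
#' @param F external field (constant).
#' @param iota encounter rate (constant, >= 0).
#' @param pi_rate net birth/death rate (constant).
#' @param mu,mu_bar,mu_tilde total, velocity-weighted and p-weighted mass:
#'   each a single number (constant in time) or a function of t, e.g. an
#'   interpolant of a kinetic run's moment series.
#' @param p,q moment orders for the (p, q) equation.
#' @param sign_mode \code{"theorem4_consistent"} (default) or
#'   \code{"as_printed"}; see Details.
#' @return An object of class \code{"riccati_params"}.
#' @export
riccati_params <- function(F, iota, pi_rate, mu, mu_bar, mu_tilde = NULL,
                           p = 1L, q = 1L,
                           sign_mode = c("theorem4_consistent",
                                         "as_printed")) {
  sign_mode <- match.arg(sign_mode)
  for (nm in c("F", "iota", "pi_rate"))
    if (!is.numeric(get(nm)) || length(get(nm)) != 1L ||
        !is.finite(get(nm)))
      ktap_stop("invalid-parameter", "%s must be a finite constant", nm)
  structure(list(
    F = F, iota = iota, pi_rate = pi_rate,
    mu = .time_fn(mu, "mu"), mu_const = is.numeric(mu),
    mu_bar = .time_fn(mu_bar, "mu_bar"), mu_bar_const = is.numeric(mu_bar),
    mu_tilde = if (is.null(mu_tilde)) NULL else .time_fn(mu_tilde,
                                                         "mu_tilde"),
    p = as.integer(p), q = as.integer(q), sign_mode = sign_mode
  ), class = "riccati_params")
}

.time_fn <- function(x, what) {
  if (is.numeric(x) && length(x) == 1L && is.finite(x)) {
    force(x); function(t) rep(x, length(t))
  } else if (is.function(x)) x
  else ktap_stop("invalid-parameter",
                 "%s must be a constant or a function of t", what)
}

#' Right-hand side of the E1 Riccati equation
#'
#' @param E1 current value of the first activation moment.
#' @param t time (used only through time-dependent mu, mu_bar).
#' @param params a \code{\link{riccati_params}}.
#' @return dE1/dt.
#' @export
riccati_rhs_E1 <- function(E1, t, params) {
  stopifnot(inherits(params, "riccati_params"))
  params$F * (params$mu_bar(t) - E1^2) -
    params$iota * (1 - params$pi_rate) * params$mu(t) * E1
}

#' Nonnegative constant solution of the E1 equation
#'
#' With constant coefficients (the conservative regime pi = 0, in which mu
#' and mu_bar are genuinely constant) the Riccati equation has the
#' nonnegative equilibrium
#'
#'   E1_bar = ( sqrt(c^2 + 4 F^2 mu_bar) - c ) / (2 F),  c = iota (1-pi) mu.
#'
#' @param F nonzero constant field (the F = 0 regime is linear and has no
#'   such root; use \code{\link{solve_moment_ode_E1}} there).
#' @param iota,pi_rate,mu,mu_bar constants.
#' @return The nonnegative root; \code{\link{riccati_rhs_E1}} vanishes
#'   there to roundoff.
#' @export
riccati_fixed_point <- function(F, iota, pi_rate, mu, mu_bar) {
  if (!is.numeric(F) || F == 0)
    ktap_stop("division-error",
              "F = 0: the E1 equation is linear there (exponential regime); use solve_moment_ode_E1")
  cc <- iota * (1 - pi_rate) * mu
  disc <- cc^2 + 4 * F^2 * mu_bar
  if (disc < 0)
    ktap_stop("domain-error",
              "negative discriminant c^2 + 4 F^2 mu_bar = %g", disc)
  (sqrt(disc) - cc) / (2 * F)
}

#' Closed-form E1 trajectory (constant-coefficient regime)
#'
#' For constant mu and mu_bar, the general solution is built from the
#' constant root E1_bar and the linear equation for lambda = 1/(E1 -
#' E1_bar):
#'
#'   lambda' = s lambda + F,  s = c + 2 F E1_bar = sqrt(c^2 + 4 F^2 mu_bar),
#'
#' solved by the integrating factor, giving E1(t) = E1_bar + 1/lambda(t).
#' Trajectories starting below the negative root escape to -infinity in
#' finite time; a requested time at or beyond that singularity raises an
#' error naming the singular time rather than returning values.
#'
#' @param t vector of requested times (>= 0).
#' @param E1_0 initial value at t = 0.
#' @param params a \code{\link{riccati_params}} with constant mu, mu_bar
#'   (verified by sampling) and F != 0.
#' @return Numeric vector of E1 values at \code{t}.
#' @export
riccati_closed_form <- function(t, E1_0, params) {
  stopifnot(inherits(params, "riccati_params"))
  ts <- seq(0, max(t, 1), length.out = 7)
  if (diff(range(params$mu(ts))) != 0 ||
      diff(range(params$mu_bar(ts))) != 0)
    ktap_stop("unsupported-regime",
              "time-dependent mu or mu_bar: use solve_moment_ode_E1")
  if (params$F == 0)
    ktap_stop("division-error",
              "F = 0: use solve_moment_ode_E1 for the linear regime")
  F <- params$F
  mu <- params$mu(0); mu_bar <- params$mu_bar(0)
  Ebar <- riccati_fixed_point(F, params$iota, params$pi_rate, mu, mu_bar)
  if (E1_0 == Ebar) return(rep(Ebar, length(t)))
  cc <- params$iota * (1 - params$pi_rate) * mu
  s <- cc + 2 * F * Ebar # = sqrt(c^2 + 4 F^2 mu_bar) >= 0
  lam0 <- 1 / (E1_0 - Ebar)
  lam <- if (s > 0) (lam0 + F / s) * exp(s * t) - F / s
         else lam0 + F * t
  # lambda is monotone; a sign change marks the finite-time escape
  if (any(lam == 0) || any(sign(lam) != sign(lam0))) {
    t_sing <- if (s > 0) log((F / s) / (lam0 + F / s)) / s
              else -lam0 / F
    ktap_stop("singularity",
              "trajectory escapes to -infinity at t = %g before a requested time",
              t_sing)
  }
  out <- Ebar + 1 / lam
  out[t == 0] <- E1_0
  out
}

#' Numerical solution of the E1 moment equation
#'
#' Adaptive high-accuracy integration (lsoda, relative tolerance 1e-10) of
#' the E1 Riccati equation; mu and mu_bar may be time dependent, e.g.
#' interpolants of a kinetic run's measured moment series.
#'
#' @param E1_0 initial value at \code{times[1]}.
#' @param times increasing time grid.
#' @param params a \code{\link{riccati_params}}.
#' @return Numeric vector of E1 at \code{times}.
#' @export
solve_moment_ode_E1 <- function(E1_0, times, params) {
  stopifnot(inherits(params, "riccati_params"))
  rhs <- function(t, y, p) list(riccati_rhs_E1(y, t, params))
  .run_ode(E1_0, times, rhs)
}

#' Numerical solution of the (p, q) moment equation
#'
#' Integrates
#'
#'   dE/dt = p F E_lower(t) (mu_tilde(t) - E) +/- iota mu(t) (1 - pi) E,
#'
#' where E_lower(t) supplies the lower moment E_{p,q-1} (the hierarchy is
#' not closed; the caller provides it, typically from a kinetic run or a
#' recursive solve) and the sign of the interaction term follows
#' \code{params$sign_mode}.
#'
#' @param E_0 initial value at \code{times[1]}.
#' @param times increasing time grid.
#' @param params a \code{\link{riccati_params}} with \code{mu_tilde} set
#'   when \code{p * F != 0}.
#' @param E_lower_fn function of t supplying E_{p,q-1}; required when
#'   \code{p * F != 0}.
#' @return Numeric vector of E values at \code{times}.
#' @export
solve_moment_ode_pq <- function(E_0, times, params, E_lower_fn = NULL) {
  stopifnot(inherits(params, "riccati_params"))
  drive <- params$p * params$F != 0
  if (drive && is.null(E_lower_fn))
    ktap_stop("missing-dependency",
              "p * F != 0 requires E_lower_fn supplying E_{p,q-1}(t)")
  if (drive && is.null(params$mu_tilde))
    ktap_stop("missing-dependency",
              "p * F != 0 requires mu_tilde in the parameters")
  sgn <- if (params$sign_mode == "as_printed") 1 else -1
  rhs <- function(t, y, p) {
    d <- sgn * params$iota * params$mu(t) * (1 - params$pi_rate) * y
    if (drive)
      d <- d + params$p * params$F * E_lower_fn(t) *
        (params$mu_tilde(t) - y)
    list(d)
  }
  .run_ode(E_0, times, rhs)
}

.run_ode <- function(y0, times, rhs) {
  if (length(times) < 2L || any(diff(times) <= 0))
    ktap_stop("invalid-parameter", "times must be strictly increasing")
  sol <- suppressWarnings(
    try(deSolve::ode(y = c(E = y0), times = times, func = rhs,
                     parms = NULL, method = "lsoda",
                     rtol = 1e-10, atol = 1e-12), silent = TRUE)
  )
  if (inherits(sol, "try-error"))
    ktap_stop("integrator-failure", "moment ODE integration failed: %s",
              attr(sol, "condition")$message)
  y <- sol[, 2L]
  if (any(!is.finite(y)) || nrow(sol) < length(times)) {
    bad <- if (nrow(sol) < length(times)) sol[nrow(sol), 1L]
           else times[which(!is.finite(y))[1L]]
    ktap_stop("integrator-failure",
              "moment ODE breakdown near t = %g", bad)
  }
  unname(y)
}
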