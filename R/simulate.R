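#' Time-integration settings
#'
#' @param t_end final time (> 0).
#' @param dt_max upper bound on the step size.
#' @param cfl Courant number in (0, 1] for the upwind transport bound
#'   \code{cfl * du / max |a|}, where a is the (damped) advective face
#'   speed.
#' @param record_every record a moment entry every this many steps (the
#'   initial state is always recorded).
#' @param blowup_mass abort threshold on the total mass mu; the
#'   nonconservative framework admits finite-time blow-up, which is
#'   detected and reported rather than regularized.
#' @param safety factor in the interaction-stiffness bound
#'   \code{safety / (iota_max * mu * (1 + max|pi|))} that keeps the
#'   explicit interaction update contractive.
#' @param tol_neg tolerated transient undershoot of f below zero; anything
#'   below \code{-tol_neg} aborts the run (clipping would silently break
#'   the conservation diagnostics).
#' @param pq_pairs moment pairs recorded along the trajectory.
#' @param keep_snapshots store the full state at every record time (the
#'   initial and final states are always kept).
#' @param seed integer seed echoed into run summaries (the integrator
#'   itself is deterministic; the seed governs sampled validation draws).
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(t_end, dt_max = 0.1, cfl = 0.9, record_every = 5L,
                       blowup_mass = 1e4, safety = 0.5, tol_neg = 1e-10,
                       pq_pairs = list(c(1L, 1L), c(2L, 2L)),
                       keep_snapshots = FALSE, seed = 1L) {
  if (!is.numeric(t_end) || t_end <= 0)
    ktap_stop("invalid-parameter", "t_end must be > 0")
  if (!is.numeric(dt_max) || dt_max <= 0)
    ktap_stop("invalid-parameter", "dt_max must be > 0")
  if (!is.numeric(cfl) || cfl <= 0 || cfl > 1)
    ktap_stop("invalid-parameter", "cfl must lie in (0, 1]")
  if (!is.numeric(record_every) || record_every < 1)
    ktap_stop("invalid-parameter", "record_every must be >= 1")
  structure(list(
    t_end = t_end, dt_max = dt_max, cfl = cfl,
    record_every = as.integer(record_every), blowup_mass = blowup_mass,
    safety = safety, tol_neg = tol_neg, pq_pairs = pq_pairs,
    keep_snapshots = isTRUE(keep_snapshots), seed = as.integer(seed)
  ), class = "run_config")
}

#' Stable explicit step size
#'
#' \code{dt = min(dt_max, cfl * du / max|a|, safety / (iota_max * mu *
#' (1 + max|pi|)))}: the middle bound is the upwind CFL condition on the
#' damped advective speed \code{a_i(u) = F_i(u) (1 - u E1 [thermostat])};
#' the last keeps the explicit quadratic interaction update contractive.
#' Inactive bounds (zero speed, zero rate) drop out.
#'
#' @param f current n x M state.
#' @param model a \code{"ktap_model"}.
#' @param cfg a \code{\link{run_config}}.
#' @return A single positive step size.
#' @export
stable_dt <- function(f, model, cfg) {
  check_state(f, model)
  kern <- model$kernels
  mu <- moment_pq(f, model, 0L, 0L)
  E1 <- moment_pq(f, model, 1L, 1L)
  damp <- if (model$thermostat) 1 - model$grid$faces * E1 else 1
  amax <- max(abs(model$F_faces * rep(damp, each = model$velocities$n)))
  bounds <- cfg$dt_max
  if (amax > 0) bounds <- c(bounds, cfg$cfl * model$grid$du / amax)
  rate <- kern$iota_max * abs(mu) * (1 + kern$pi_abs_max)
  if (rate > 0) bounds <- c(bounds, cfg$safety / rate)
  dt <- min(bounds)
  if (!is.finite(dt) || dt <= 0)
    ktap_stop("configuration-error", "no finite positive step size")
  dt
}

#' One classical Runge-Kutta (RK4) step
#'
#' Advances the state by one explicit 4-stage step of the full kinetic
#' right-hand side. The first activation moment inside the thermostat is
#' recomputed at every stage: the damping is a state-dependent
#' nonlinearity, not a frozen coefficient.
#'
#' @inheritParams stable_dt
#' @param dt step size (> 0).
#' @return The updated n x M state.
#' @export
step_rk4 <- function(f, model, dt) {
  if (!is.numeric(dt) || dt <= 0)
    ktap_stop("invalid-parameter", "dt must be > 0")
  k1 <- kinetic_rhs(f, model)
  k2 <- kinetic_rhs(f + dt / 2 * k1, model)
  k3 <- kinetic_rhs(f + dt / 2 * k2, model)
  k4 <- kinetic_rhs(f + dt * k3, model)
  out <- f + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(!is.finite(out))) {
    bad <- which(!is.finite(out), arr.ind = TRUE)[1L, ]
    ktap_stop("numerical-error",
              "non-finite state after step at class i = %d, cell k = %d",
              bad[1L], bad[2L])
  }
  out
}

#' Integrate the kinetic equation
#'
#' Advances the state with \code{\link{step_rk4}} and the adaptive bound of
#' \code{\link{stable_dt}} until \code{t_end}, mass blow-up or a negativity
#' abort. Moment records are kept every \code{record_every} steps. When the
#' total mass crosses \code{blowup_mass}, the crossing time is estimated by
#' linear interpolation in 1/mu (the natural variable near quadratic
#' blow-up, where 1/mu decays linearly) and reported as
#' \code{blowup_time_estimate}.
#'
#' @param model a \code{"ktap_model"}.
#' @param f0 initial n x M state (see \code{\link{initial_state}}).
#' @param cfg a \code{\link{run_config}}.
#' @param verbose print a progress line at every record step.
#' @return An object of class \code{"ktap_run"}: list with \code{moments}
#'   (data frame), \code{status} (one of \code{"completed"},
#'   \code{"blowup_detected"}, \code{"negativity_abort"}), \code{final}
#'   state, \code{snapshots}, \code{blowup_time_estimate},
#'   \code{min_f_observed}, \code{n_steps}, and the model/config used.
#' @examples
#' sc <- ktap_scenario("conservative-uniform", M = 20)
#' r <- run_kinetic(sc$model, sc$f0, run_config(t_end = 1))
#' r
#' @export
run_kinetic <- function(model, f0, cfg, verbose = FALSE) {
  stopifnot(inherits(model, "ktap_model"), inherits(cfg, "run_config"))
  check_state(f0, model)
  f <- f0; t <- 0; step <- 0L
  min_f <- min(f)
  records <- list(moment_record(f, model, time = 0,
                                pq_pairs = cfg$pq_pairs))
  snapshots <- list(list(time = 0, values = f))
  status <- "completed"
  blowup_t <- NA_real_
  mu_prev <- records[[1L]]$mu; t_prev <- 0
  while (t < cfg$t_end - 1e-12) {
    dt <- min(stable_dt(f, model, cfg), cfg$t_end - t)
    f <- step_rk4(f, model, dt)
    t <- t + dt; step <- step + 1L
    mn <- min(f); if (mn < min_f) min_f <- mn
    mu <- sum(f) * model$grid$du
    if (mn < -cfg$tol_neg) {
      status <- "negativity_abort"
    } else if (mu > cfg$blowup_mass) {
      status <- "blowup_detected"
      # linear interpolation in 1/mu between the bracketing steps
      w <- (1 / mu_prev - 1 / cfg$blowup_mass) / (1 / mu_prev - 1 / mu)
      blowup_t <- t_prev + w * (t - t_prev)
    }
    record_now <- step %% cfg$record_every == 0L ||
      t >= cfg$t_end - 1e-12 || status != "completed"
    if (record_now) {
      rec <- moment_record(f, model, time = t, pq_pairs = cfg$pq_pairs)
      records[[length(records) + 1L]] <- rec
      if (cfg$keep_snapshots)
        snapshots[[length(snapshots) + 1L]] <- list(time = t, values = f)
      if (verbose)
        cat(sprintf("t = %-10.5g dt = %-10.4g mu = %-12.6g E1 = %-12.6g min f = %.3g\n",
                    t, dt, rec$mu, rec$E_pq[["E_1_1"]], mn))
    }
    if (status != "completed") break
    mu_prev <- mu; t_prev <- t
  }
  if (!cfg$keep_snapshots || snapshots[[length(snapshots)]]$time < t)
    snapshots[[length(snapshots) + 1L]] <- list(time = t, values = f)
  structure(list(
    moments = moment_series_df(records), status = status,
    final = f, final_time = t, snapshots = snapshots,
    blowup_time_estimate = blowup_t, min_f_observed = min_f,
    n_steps = step, model = model, config = cfg
  ), class = "ktap_run")
}

#' @export
print.ktap_run <- function(x, ...) {
  cat(sprintf("kinetic run: %d steps to t = %g, status: %s\n",
              x$n_steps, x$final_time, x$status))
  last <- x$moments[nrow(x$moments), ]
  cat(sprintf("  mu = %.6g, E_1_1 = %.6g, min f observed = %.3g\n",
              last$mu, last$E_1_1, x$min_f_observed))
  if (!is.na(x$blowup_time_estimate))
    cat(sprintf("  estimated blow-up time: %.6g\n", x$blowup_time_estimate))
  invisible(x)
}

#' @export
summary.ktap_run <- function(object, ...) {
  m <- object$moments
  cat(sprintf("kinetic run over t in [0, %g] (%d steps, %d records)\n",
              object$final_time, object$n_steps, nrow(m)))
  cat(sprintf("  status: %s\n", object$status))
  cat(sprintf("  mass mu:    %.6g -> %.6g (rel change %.3g)\n",
              m$mu[1], m$mu[nrow(m)],
              (m$mu[nrow(m)] - m$mu[1]) / max(abs(m$mu[1]), 1e-300)))
  cat(sprintf("  E_1_1:      %.6g -> %.6g\n", m$E_1_1[1], m$E_1_1[nrow(m)]))
  cat(sprintf("  min f observed: %.3g\n", object$min_f_observed))
  if (!is.na(object$blowup_time_estimate))
    cat(sprintf("  estimated blow-up time: %.6g\n",
                object$blowup_time_estimate))
  invisible(object)
}

#' @export
as.data.frame.ktap_run <- function(x, ...) x$moments

#' @export
plot.ktap_run <- function(x, which = c("moments", "state"), ...) {
  which <- match.arg(which)
  m <- x$moments
  if (which == "moments") {
    matplot(m$time, cbind(m$mu, m$E_1_1), type = "l", lty = 1:2,
            col = c(1, 2), xlab = "t", ylab = "moment", ...)
    legend("topright", c("mu", "E_1_1"), lty = 1:2, col = c(1, 2),
           bty = "n")
  } else {
    u <- x$model$grid$centers
    matplot(u, t(x$final), type = "l", lty = 1, xlab = "u",
            ylab = "f_i(u)", ...)
  }
  invisible(x)
}

#' Approximate a stationary state by long-time integration
#'
#' Integrates until the sup norm of the full right-hand side falls below
#' \code{tol} (checked every \code{record_every} steps) or \code{t_cap} is
#' reached. Existence of stationary solutions in the nonconservative
#' regime is an open question; in mass-growing regimes the flag simply
#' comes back \code{FALSE}.
#'
#' @inheritParams run_kinetic
#' @param tol residual tolerance on \code{max |kinetic_rhs|}.
#' @param t_cap time budget for the relaxation.
#' @return List with \code{state}, \code{converged}, \code{time},
#'   \code{residual}.
#' @export
steady_state <- function(model, f0, tol = 1e-8, t_cap = 50,
                         cfg = run_config(t_end = t_cap)) {
  stopifnot(inherits(model, "ktap_model"))
  check_state(f0, model)
  if (tol <= 0) ktap_stop("invalid-parameter", "tol must be > 0")
  f <- f0; t <- 0; step <- 0L
  res <- max(abs(kinetic_rhs(f, model)))
  while (res > tol && t < t_cap) {
    dt <- min(stable_dt(f, model, cfg), t_cap - t)
    f <- step_rk4(f, model, dt)
    t <- t + dt; step <- step + 1L
    if (min(f) < -cfg$tol_neg || sum(f) * model$grid$du > cfg$blowup_mass)
      break
    if (step %% cfg$record_every == 0L)
      res <- max(abs(kinetic_rhs(f, model)))
  }
  res <- max(abs(kinetic_rhs(f, model)))
  list(state = f, converged = res <= tol, time = t, residual = res)
}
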