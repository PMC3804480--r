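#' Velocity-activity moments of the hybrid distribution
#'
#' The (p, q) moment of the discrete-velocity family f_i(t, u) is
#'
#'   E_{p,q} = sum_i v_i^p * integral u^q f_i(u) du,
#'
#' evaluated with the same midpoint rule as the operators, so discrete
#' moment identities obtained by integration by parts hold up to the
#' transport scheme's truncation error only. The convention 0^0 = 1 makes
#' E_{0,0} the total mass mu.
#'
#' @param f n x M state matrix.
#' @param model a \code{"ktap_model"}.
#' @param p,q nonnegative integer moment orders (p weighs velocity, q
#'   activity).
#' @return A single number.
#' @examples
#' sc <- ktap_scenario("conservative-uniform")
#' moment_pq(sc$f0, sc$model, 0, 0) # total mass, 1
#' @export
moment_pq <- function(f, model, p, q) {
  check_state(f, model)
  if (!is.numeric(p) || !is.numeric(q) || p < 0 || q < 0 ||
      p != round(p) || q != round(q))
    ktap_stop("invalid-parameter", "p and q must be nonnegative integers")
  v <- model$velocities$values
  u <- model$grid$centers
  sum((v ^ p) * (f %*% (u ^ q))) * model$grid$du
}

#' Full moment record of a state
#'
#' Computes, at one instant, the per-class masses mu_i, the total mass mu,
#' the velocity-weighted mass mu_bar = sum v_i mu_i, the generalized
#' weights mu_tilde(p) = sum v_i^p mu_i, and the moments E_{p,q} for the
#' requested (p, q) pairs (E_{1,1}, the controlled activation moment, is
#' always included).
#'
#' @inheritParams moment_pq
#' @param time time stamp carried in the record.
#' @param pq_pairs list of integer pairs c(p, q) to evaluate.
#' @param p_list integer orders for mu_tilde.
#' @return An object of class \code{"moment_record"}.
#' @export
moment_record <- function(f, model, time = 0,
                          pq_pairs = list(c(1L, 1L)), p_list = 0:2) {
  check_state(f, model)
  du <- model$grid$du
  v <- model$velocities$values
  mu_i <- as.vector(f %*% rep(1, model$grid$M)) * du
  pq_pairs <- unique(c(list(c(1L, 1L)), pq_pairs))
  E <- vapply(pq_pairs, function(pq) moment_pq(f, model, pq[1], pq[2]), 0)
  names(E) <- vapply(pq_pairs, function(pq)
    sprintf("E_%d_%d", pq[1], pq[2]), "")
  mu_tilde <- vapply(p_list, function(p) sum(v ^ p * mu_i), 0)
  names(mu_tilde) <- paste0("p", p_list)
  structure(list(
    time = time, mu_i = mu_i, mu = sum(mu_i),
    mu_bar = sum(v * mu_i), mu_tilde = mu_tilde, E_pq = E
  ), class = "moment_record")
}

#' @export
print.moment_record <- function(x, ...) {
  cat(sprintf("t = %g: mu = %.6g, mu_bar = %.6g, E_1_1 = %.6g\n",
              x$time, x$mu, x$mu_bar, x$E_pq[["E_1_1"]]))
  invisible(x)
}

# Flatten a list of moment records into the canonical data frame used by
# the run result and the CSV writer: time, mu, mu_bar, then one column per
# requested (p, q) pair, in the deterministic order of the first record.
moment_series_df <- function(records) {
  stopifnot(length(records) >= 1L)
  cols <- names(records[[1L]]$E_pq)
  df <- data.frame(
    time = vapply(records, `[[`, 0, "time"),
    mu = vapply(records, `[[`, 0, "mu"),
    mu_bar = vapply(records, `[[`, 0, "mu_bar")
  )
  for (cn in cols)
    df[[cn]] <- vapply(records, function(r) r$E_pq[[cn]], 0)
  df
}
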