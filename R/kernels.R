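#' Interaction kernels of the hybrid kinetic model
#'
#' Bundles the three kernels governing binary encounters between velocity
#' classes i (test/candidate) and j (field):
#' \itemize{
#'   \item \code{iota}: nonnegative encounter rate iota_ij(u1, u2);
#'   \item \code{transition}: the probability density A_ij(u1, u2, u) over
#'     the outgoing activity (see \code{\link{transition_uniform}});
#'   \item \code{pi_rate}: net birth/death rate pi_ij(u1, u2), which may be
#'     negative (net destruction).
#' }
#' Rates are evaluated once at cell centers and stored as M x M matrices per
#' (i, j) pair.
#'
#' @param grid an \code{\link{activity_grid}}.
#' @param n number of velocity classes.
#' @param iota encounter rate: a single nonnegative number, a vectorized
#'   function \code{f(u1, u2)} shared by all pairs, or a function
#'   \code{f(i, j, u1, u2)}.
#' @param transition a \code{"ktap_transition"} shared by all pairs, or a
#'   list of n^2 of them in row-major (i, j) order.
#' @param pi_rate net birth/death rate, same calling forms as \code{iota}.
#' @return An object of class \code{"ktap_kernels"}.
#' @export
interaction_kernels <- function(grid, n, iota = 1, transition,
                                pi_rate = 0) {
  stopifnot(inherits(grid, "activity_grid"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    ktap_stop("invalid-parameter", "n must be a positive integer")
  iota_k <- .rate_mats(grid, n, iota, "iota")
  pi_k   <- .rate_mats(grid, n, pi_rate, "pi")
  if (any(vapply(iota_k$mats, min, 0) < 0))
    ktap_stop("invalid-parameter", "iota must be nonnegative everywhere")
  if (inherits(transition, "ktap_transition")) {
    trs <- list(transition); tr_shared <- TRUE
  } else if (is.list(transition) && length(transition) == n * n &&
             all(vapply(transition, inherits, TRUE, "ktap_transition"))) {
    trs <- transition; tr_shared <- FALSE
  } else {
    ktap_stop("invalid-parameter",
              "transition must be a ktap_transition or a list of n^2 of them")
  }
  for (tr in trs)
    if (tr$grid$M != grid$M)
      ktap_stop("dimension-mismatch",
                "transition density built on a different grid (M = %d vs %d)",
                tr$grid$M, grid$M)
  structure(list(
    grid = grid, n = n,
    iota_mats = iota_k$mats, iota_const = iota_k$const,
    iota_value = iota_k$value,
    pi_mats = pi_k$mats, pi_const = pi_k$const, pi_value = pi_k$value,
    transitions = trs, tr_shared = tr_shared,
    iota_max = max(vapply(iota_k$mats, max, 0)),
    pi_abs_max = max(vapply(pi_k$mats, function(m) max(abs(m)), 0))
  ), class = "ktap_kernels")
}

# Build the per-pair M x M rate matrices for a scalar / f(u1,u2) /
# f(i,j,u1,u2) specification. Returns mats (length n^2, row-major (i,j)),
# a constant flag and, when constant, the value.
.rate_mats <- function(grid, n, spec, what) {
  u <- grid$centers
  if (is.numeric(spec) && length(spec) == 1L) {
    if (!is.finite(spec))
      ktap_stop("invalid-parameter", "%s must be finite", what)
    m <- matrix(spec, grid$M, grid$M)
    return(list(mats = rep(list(m), n * n), const = TRUE,
                value = as.numeric(spec)))
  }
  if (is.function(spec)) {
    nargs <- length(formals(spec))
    mats <- vector("list", n * n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      m <- if (nargs >= 4L) outer(u, u, function(a, b) spec(i, j, a, b))
           else outer(u, u, spec)
      if (any(!is.finite(m)))
        ktap_stop("invalid-parameter", "%s evaluates to non-finite values",
                  what)
      mats[[(i - 1L) * n + j]] <- m
    }
    rng <- range(unlist(lapply(mats, range)))
    return(list(mats = mats, const = diff(rng) == 0, value = rng[1]))
  }
  ktap_stop("invalid-parameter",
            "%s must be a number or a function of (u1, u2) or (i, j, u1, u2)",
            what)
}

kernel_iota <- function(kern, i, j) kern$iota_mats[[(i - 1L) * kern$n + j]]
kernel_pi   <- function(kern, i, j) kern$pi_mats[[(i - 1L) * kern$n + j]]
kernel_transition <- function(kern, i, j) {
  if (kern$tr_shared) kern$transitions[[1L]]
  else kern$transitions[[(i - 1L) * kern$n + j]]
}

#' @export
print.ktap_kernels <- function(x, ...) {
  cat(sprintf(
    "interaction kernels, n = %d:\n  iota: %s\n  pi:   %s\n  A:    %s%s\n",
    x$n,
    if (x$iota_const) sprintf("constant %g", x$iota_value) else "varying",
    if (x$pi_const) sprintf("constant %g", x$pi_value) else "varying",
    x$transitions[[1L]]$type,
    if (x$tr_shared) " (shared)" else " (per pair)"))
  invisible(x)
}

#' Validate a model's kernels by seeded sampling
#'
#' Draws \code{n_samples} incoming configurations (i, j, u1, u2) and checks
#' the discrete sum rule of the transition density (its midpoint integral
#' over the outgoing activity must equal 1 to within 1e-12), nonnegativity
#' of the encounter rate and of the density, and reports the discrete mean
#' of the density (the zero-mean diagnostic used by the moment-ODE
#' cross-validation harness).
#'
#' @param model a \code{"ktap_model"} (see \code{\link{kinetic_model}}).
#' @param n_samples number of seeded draws.
#' @param seed integer seed for the draws.
#' @return An object of class \code{"ktap_validation"}: a list with
#'   \code{max_norm_error}, \code{min_iota}, \code{min_A},
#'   \code{max_abs_mean} (of the transition density), and a logical
#'   \code{pass}.
#' @export
validate_model <- function(model, n_samples = 10L, seed = 1L) {
  stopifnot(inherits(model, "ktap_model"))
  kern <- model$kernels
  g <- model$grid
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  n <- kern$n
  ii <- sample.int(n, n_samples, replace = TRUE)
  jj <- sample.int(n, n_samples, replace = TRUE)
  k1 <- sample.int(g$M, n_samples, replace = TRUE)
  k2 <- sample.int(g$M, n_samples, replace = TRUE)
  norm_err <- minA <- absmean <- numeric(n_samples)
  for (s in seq_len(n_samples)) {
    dens <- transition_slice(kernel_transition(kern, ii[s], jj[s]),
                             k1[s], k2[s])
    norm_err[s] <- abs(sum(dens) * g$du - 1)
    minA[s] <- min(dens)
    absmean[s] <- abs(sum(g$centers * dens) * g$du)
  }
  min_iota <- min(vapply(kern$iota_mats, min, 0))
  out <- list(
    n_samples = n_samples, seed = as.integer(seed),
    max_norm_error = max(norm_err),
    min_iota = min_iota,
    min_A = min(minA),
    max_abs_mean = max(absmean),
    pass = max(norm_err) <= 1e-12 && min_iota >= 0 && min(minA) >= 0
  )
  class(out) <- "ktap_validation"
  out
}

#' @export
print.ktap_validation <- function(x, ...) {
  cat(sprintf(paste0(
    "kernel validation (%d seeded draws):\n",
    "  max |sum(A)*du - 1| : %.3e\n",
    "  min iota            : %g\n",
    "  min A               : %g\n",
    "  max |mean_u A|      : %.3e\n",
    "  pass: %s\n"),
    x$n_samples, x$max_norm_error, x$min_iota, x$min_A, x$max_abs_mean,
    if (x$pass) "yes" else "NO"))
  invisible(x)
}
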