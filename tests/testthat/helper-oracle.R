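# Independent brute-force implementations of the three interaction
# operators, written as literal triple loops over the discrete grid from
# their integral definitions. Kernel values are evaluated from the raw
# iota/pi functions and the transition object, not from the package's
# precomputed per-pair matrices.

oracle_gain <- function(f, model, iota_fn, tr) {
  g <- model$grid; u <- g$centers; du <- g$du
  n <- nrow(f); M <- g$M
  G <- matrix(0, n, M)
  for (i in seq_len(n)) for (k in seq_len(M)) {
    acc <- 0
    for (j in seq_len(n)) for (k1 in seq_len(M)) for (k2 in seq_len(M))
      acc <- acc + iota_fn(u[k1], u[k2]) *
        transition_slice(tr, k1, k2)[k] * f[i, k1] * f[j, k2] * du^2
    G[i, k] <- acc
  }
  G
}

oracle_loss <- function(f, model, iota_fn) {
  g <- model$grid; u <- g$centers; du <- g$du
  n <- nrow(f); M <- g$M
  L <- matrix(0, n, M)
  for (i in seq_len(n)) for (k in seq_len(M)) {
    acc <- 0
    for (j in seq_len(n)) for (k2 in seq_len(M))
      acc <- acc + iota_fn(u[k], u[k2]) * f[j, k2] * du
    L[i, k] <- f[i, k] * acc
  }
  L
}

oracle_nonconservative <- function(f, model, iota_fn, pi_fn) {
  g <- model$grid; u <- g$centers; du <- g$du
  n <- nrow(f); M <- g$M
  N <- matrix(0, n, M)
  for (i in seq_len(n)) for (k in seq_len(M)) {
    acc <- 0
    for (j in seq_len(n)) for (k2 in seq_len(M))
      acc <- acc + iota_fn(u[k], u[k2]) * pi_fn(u[k], u[k2]) *
        f[j, k2] * du
    N[i, k] <- f[i, k] * acc
  }
  N
}
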