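# Shared builders for small test models. Kernels are passed around as the
# raw ingredients (iota function, transition object, pi function) so the
# brute-force oracle can evaluate them independently of the package's
# precomputed matrices.

make_model <- function(M = 8, v = 1, iota = 1, pi_rate = 0, force = 0,
                       thermostat = FALSE, u_min = -1, u_max = 1,
                       transition = NULL) {
  g <- activity_grid(u_min, u_max, M)
  if (is.null(transition)) transition <- transition_uniform(g)
  kern <- interaction_kernels(g, length(v), iota = iota,
                              transition = transition, pi_rate = pi_rate)
  kinetic_model(g, velocity_set(v), kern, force = force,
                thermostat = thermostat)
}

rand_state <- function(model, seed = 1) {
  set.seed(seed)
  matrix(runif(model$velocities$n * model$grid$M, 0.1, 1),
         model$velocities$n, model$grid$M)
}
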