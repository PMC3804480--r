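grid:
  u_min: -1.0
  u_max: 1.0
  M: 200
velocities: [1.0]
kernels:
  iota: 1.0
  A:
    type: uniform
  pi: 0.0
force: 1.0
thermostat: true
initial:
  expr: "0.75*(1 - u^2)"
  mass: 1.0
run:
  t_end: 5.0
  record_every: 2
output:
  prefix: thermostated
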