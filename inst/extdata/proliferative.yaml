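grid:
  u_min: -1.0
  u_max: 1.0
  M: 100
velocities: [1.0]
kernels:
  iota: 1.0
  A:
    type: uniform
  pi: 0.5
force: 0.0
thermostat: false
initial:
  expr: "0.5 + 0*u"
  mass: 1.0
run:
  t_end: 3.0
  dt_max: 0.05
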