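{
  "_comment": "Desk-scale mobility scan around the critical mobility at L=100, T=N: minutes on one CPU.",
  "base": {"L": 100, "M": 1e-4, "T_max": 10000, "seed": 1, "record_every": 10000},
  "sweep_variable": "M",
  "values": [1e-4, 2e-4, 4e-4, 8e-4],
  "replicates": 20,
  "measurement": "phase_state"
}
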