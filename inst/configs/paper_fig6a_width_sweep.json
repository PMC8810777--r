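{
  "_comment": "Reference interface-width sweep: W at t=1000, 30 replicates, L=300. Run once with base M=1e-5 and once with 1e-3. Feasible on a workstation (minutes-hours).",
  "base": {"L": 300, "M": 1e-5, "T_max": 1000, "seed": 1, "record_every": 1000},
  "sweep_variable": "k",
  "values": [0.5, 2, 5, 10, 20],
  "replicates": 30,
  "measurement": "width_at_t",
  "t_measure": 1000
}
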