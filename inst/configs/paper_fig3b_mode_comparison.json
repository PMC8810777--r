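{
  "_comment": "Reference traditional-vs-territorial comparison (run through sweep_traditional_vs_territorial): matched seeds, censored at 810,000 generations. BEYOND DESK SCALE.",
  "base": {"L": 300, "M": 1e-5, "T_max": 810000, "seed": 1, "record_every": 1},
  "sweep_variable": "k",
  "values": [2, 4, 6, 8, 10, 12, 14, 16, 18, 20],
  "replicates": 30,
  "measurement": "extinction_time_low",
  "censor_at": 810000
}
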