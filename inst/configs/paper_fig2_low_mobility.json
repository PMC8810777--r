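{
  "_comment": "Reference protocol, low mobility (density trajectories): L=300, M=1e-5, k as in the figure panels (5/10/20; set k_A=k_B=k_C). Run length 490,000 generations. BEYOND DESK SCALE: hours of CPU per run.",
  "L": 300, "M": 1e-5, "k_A": 5, "k_B": 5, "k_C": 5,
  "T_max": 490000, "seed": 1, "record_every": 100
}
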