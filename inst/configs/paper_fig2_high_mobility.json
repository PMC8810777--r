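{
  "_comment": "Reference protocol, high mobility: L=300, M=1e-3, 180,000 generations. BEYOND DESK SCALE.",
  "L": 300, "M": 1e-3, "k_A": 5, "k_B": 5, "k_C": 5,
  "T_max": 180000, "seed": 1, "record_every": 100
}
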