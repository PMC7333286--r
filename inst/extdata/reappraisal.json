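{
  "scenario": "reappraisal",
  "intervention": {"onset": 12.5, "input_level": 1},
  "simulation": {"t_max": 50, "dt_out": 0.05, "solver": "rk_adaptive"}
}
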