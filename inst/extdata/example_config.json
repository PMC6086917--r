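{
  "flow": { "U_inf_ms": 0.94, "nu_m2s": 1.56e-05 },
  "kinematics": { "f_hz": 213, "Phi_deg": 140 },
  "geometry": { "wing_area_mm2": 2.59, "span_mm": 2.87 },
  "experiment": { "ks": [0.33, 0.65, 1.30], "scale": "desk" }
}
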