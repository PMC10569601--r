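{
  "stage": "simulate",
  "kind": "ingression",
  "out_prefix": "example",
  "spec": {
    "n_frames": 12,
    "ingressions": [
      {"angle_deg": 60, "depth_um": 1.6},
      {"angle_deg": 280, "depth_um": 1.2}
    ]
  },
  "params": {"seed": 42}
}
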