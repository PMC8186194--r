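{
  "population": {"n_normal": 5000, "n_cardiomegaly": 2517, "seed": 42},
  "geometry": {"image_size": 128, "pixel_spacing": 0.7},
  "reference": "truth_mask",
  "accept_tol": 0.018
}
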