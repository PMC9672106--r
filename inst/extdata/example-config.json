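{
  "seed": 1,
  "condition": "control",
  "mode": "simulate",
  "camera": {
    "offset": 100,
    "inverse_gain": 4,
    "read_noise_sd": 0.5,
    "pixel_size": 0.16
  },
  "truth": {
    "fractions": [0.6, 0.4],
    "monomer_median": 100,
    "monomer_gsd": 1.4,
    "active_prob": 1,
    "density": 0.5
  },
  "simulate": {
    "n_cells": 5,
    "frames_per_cell": 10,
    "shape_px": [128, 128],
    "spot_density": 0.06
  },
  "monomer_calibration": { "simulate_n": 2000, "imaged": true },
  "detection": { "psf_sigma_px": 1.2, "k_sigma": 5, "window_px": 9 },
  "mixture": { "n_max": 3, "bootstrap_reps": 100, "bootstrap_frac": 0.5 },
  "pooling": "experiment",
  "out_dir": "toccsl-results"
}
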