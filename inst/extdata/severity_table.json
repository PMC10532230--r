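{
  "format_version": 1,
  "comment": "Severity magnitudes per corruption kind, levels 1-5. Fractions marked 'of_range' are relative to the input volume's observed intensity range; 'of_sd' to its standard deviation. Mirrors severity_params() in the ihf3d package.",
  "local_noise": {
    "noise_sd_of_range": [0.02, 0.05, 0.1, 0.2, 0.4],
    "blur_sigma_voxels": [0.5, 1, 2, 4, 8],
    "gamma": [1.2, 1.5, 2, 3, 5]
  },
  "elastic": {
    "max_disp_voxels": [1, 2, 4, 8, 16],
    "control_grid": 8
  },
  "kspace": {
    "amp_of_sd": [0.05, 0.1, 0.25, 0.5, 1.0],
    "count": [1, 2, 4, 8, 16]
  },
  "anisotropy": {
    "factor": [2, 3, 4, 6, 8]
  },
  "ghosting": {
    "w": [0.05, 0.1, 0.2, 0.35, 0.5],
    "n_ghosts": [2, 2, 3, 3, 4]
  },
  "motion": {
    "degrees": [1, 2, 4, 8, 15],
    "translation_voxels": [0.5, 1, 2, 4, 8],
    "n_transforms": 2
  }
}
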