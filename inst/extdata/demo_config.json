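{
  "seed": 1,
  "geometry": {
    "voxel_size": 1e-4,
    "dims": [248, 248, 40],
    "n_radial": 124,
    "n_phi": 16,
    "n_h": 10,
    "r_vial": 10.9e-3,
    "h_vial": 4e-3,
    "scan_interval": 50
  },
  "thickness": { "base": 2e-3, "gradient_frac": 0.2, "eccentricity": 0.05 },
  "phantom": { "noise_sd": 0.02, "scan_interval": 50 },
  "true_rp": { "constant": 1e5 },
  "simulate": { "P_c": 10, "P_tot": 1.2, "dt": 10, "max_time": 7200 },
  "thermal": { "frames_per_rev": 16, "rpm": 5, "noise_sd": 0.5 }
}
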