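{
  "Lorenz": {
    "gt": "lorenz.txt", "cm": null,
    "expected_fispo": true, "expected_degrees": [2, 0],
    "library_degree": 2, "t_end": 10, "n_points": 250, "n_traj": 1
  },
  "Immunity": {
    "gt": "immunity.txt", "cm": "immunity_cm.txt",
    "expected_fispo": false, "expected_degrees": [3, 1],
    "library_degree": 3, "t_end": 8, "n_points": 60, "n_traj": 8
  },
  "Bacterial": {
    "gt": "bacterial.txt", "cm": "bacterial_cm.txt",
    "expected_fispo": true, "expected_degrees": [6, 6],
    "library_degree": 6, "t_end": 8, "n_points": 60, "n_traj": 8
  },
  "Microbial": {
    "gt": "microbial.txt", "cm": "microbial_cm.txt",
    "expected_fispo": true, "expected_degrees": [2, 1],
    "library_degree": 2, "t_end": 12, "n_points": 60, "n_traj": 8
  },
  "Crypt": {
    "gt": "crypt.txt", "cm": "crypt_cm.txt",
    "expected_fispo": false, "expected_degrees": [3, 2],
    "library_degree": 3, "t_end": 10, "n_points": 60, "n_traj": 8
  },
  "Glycolysis": {
    "gt": "glycolysis.txt", "cm": "glycolysis_cm.txt",
    "expected_fispo": true, "expected_degrees": [6, 4],
    "library_degree": 5, "t_end": 10, "n_points": 80, "n_traj": 6
  }
}
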