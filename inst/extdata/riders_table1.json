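[
  {"name": "Climber",       "n": 50, "mass_kg": 63.2, "mass_sd": 4.4, "height_m": 1.77, "height_sd": 0.06, "cda_m2": 0.264, "cda_sd": 0.006, "cp_w": 354.1, "cp_sd": 24.6, "w_prime_j": 23000, "w_prime_sd": 1300, "tau_s": 0},
  {"name": "Sprinter",      "n": 11, "mass_kg": 80.2, "mass_sd": 6.5, "height_m": 1.87, "height_sd": 0.06, "cda_m2": 0.285, "cda_sd": 0.007, "cp_w": 381.3, "cp_sd": 23.7, "w_prime_j": 38600, "w_prime_sd": 4500, "tau_s": 0},
  {"name": "Time trialist", "n": 11, "mass_kg": 72.6, "mass_sd": 5.4, "height_m": 1.84, "height_sd": 0.08, "cda_m2": 0.276, "cda_sd": 0.006, "cp_w": 395.3, "cp_sd": 31.8, "w_prime_j": 22000, "w_prime_sd": 2700, "tau_s": 0},
  {"name": "GC-contender",  "n": 7,  "mass_kg": 63.8, "mass_sd": 4.5, "height_m": 1.76, "height_sd": 0.07, "cda_m2": 0.265, "cda_sd": 0.006, "cp_w": 388.6, "cp_sd": 24.0, "w_prime_j": 18100, "w_prime_sd": 2300, "tau_s": 0},
  {"name": "All-rounder",   "n": 65, "mass_kg": 69.5, "mass_sd": 5.5, "height_m": 1.81, "height_sd": 0.06, "cda_m2": 0.272, "cda_sd": 0.007, "cp_w": 361.1, "cp_sd": 31.7, "w_prime_j": 30100, "w_prime_sd": 200, "tau_s": 0}
]
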