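{
  "seed": 1,
  "output_dir": "out",
  "log_level": "info",
  "architecture": {
    "l_o_CE": 0.0378,
    "alpha_o": 32.5,
    "f_o_CE": 894.7,
    "l_s_T": 0.401,
    "v_max": 10,
    "tendon": "typical",
    "fiber_damping": 0.1,
    "tendon_damping": false
  },
  "path": { "r": 0.056 },
  "design": { "name": "fig3", "omegas_max": 200, "omegas_step": 10 },
  "synth": {
    "accel": 400,
    "trigger_fraction": 0.95,
    "gm_fraction": 0.159,
    "noise": { "torque": 0.5, "angle": 0.05, "emg": 0.02, "fascicle": 0.05 }
  }
}
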