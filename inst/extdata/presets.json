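{
  "comment": "Named parameter presets. phase_models: binary Flory-Huggins fits for poly-rA RNA in 1 M KCl at three effective chain lengths (A, B in chi(T) = A + B/T, B in kelvin, rho_solute in kg/m^3). kinetics: reference transport/kinetic parameters (SI units).",
  "phase_models": {
    "m1000": { "M": 1000, "A": 0.31, "B": 75.0,  "rho_solute": 1600 },
    "m2000": { "M": 2000, "A": 0.23, "B": 98.8,  "rho_solute": 1600 },
    "m4000": { "M": 4000, "A": 0.19, "B": 110.0, "rho_solute": 1600 }
  },
  "kinetics": {
    "polyra": {
      "theta": 1.5e-10,
      "D_plus": 1.3e-13,
      "D_minus": 1.3e-10,
      "Mw": 2500
    }
  },
  "tension": {
    "polyra_ising": { "form": "ising_T", "gamma0": 1.8e-06 },
    "polyra_fusion_const": { "form": "constant", "gamma0": 9e-07 }
  }
}
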