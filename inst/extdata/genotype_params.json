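{
  "comment": "Catalytic and leaf parameter sets per genotype/preparation. Michaelis constants on the dissolved (uM) basis, S_C/O on the molar basis; resolve_to_pressure() converts. E in umol active sites m^-2; E_fitted / kcat_fitted are the model-fit values for the transplastomic lines. gamma_printed is the reported CO2 compensation point (ubar) where available.",
  "genotypes": {
    "tobacco-WT": {
      "kcat": 3.1, "KM_RuBP": 19, "KC_N2_uM": 9.7, "KC_21O2_uM": 18.3,
      "SCO_molar": 80, "E": 21.9, "gamma_printed": 55
    },
    "CyLS": {
      "kcat": 9.8, "KM_RuBP": 38, "KC_N2_uM": 158, "KC_21O2_uM": 275,
      "SCO_molar": 55, "E": 2.1, "E_fitted": 1.8, "gamma_printed": 503
    },
    "CyLS-S1S2-free": {
      "kcat": 9.4, "KM_RuBP": 36, "KC_N2_uM": 169, "KC_21O2_uM": 285,
      "SCO_molar": 55, "sco_assumed_from": "CyLS",
      "E": 1.5, "E_fitted": 1.7, "gamma_printed": 553
    },
    "CyLS-S1S2-carboxysome": {
      "kcat": 4.9, "KM_RuBP": 59, "KC_21O2_uM": 248,
      "SCO_molar": 55, "sco_assumed_from": "CyLS",
      "kcat_fitted": 6.46
    },
    "Cyanobium-carboxysome": {
      "kcat": 9.5, "KM_RuBP": 79, "KC_21O2_uM": 242,
      "SCO_molar": 55, "sco_assumed_from": "CyLS"
    }
  }
}
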