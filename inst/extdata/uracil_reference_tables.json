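{
  "comment": "Published CAM-B3LYP/aug-cc-pVDZ reference values for uracil in gas phase and water (PCM), stored verbatim as printed. Dipoles in Debye, beta in a.u., wavenumbers in cm-1, I_IR in km/mol, A_Raman in A^4/amu.",
  "units": {
    "mu": "debye",
    "beta": "au",
    "wavenumber": "cm1",
    "I_IR": "km/mol",
    "A_Raman": "A4/amu",
    "hw": "au"
  },
  "table1": {
    "gas": {
      "mu_x": 1.21, "mu_z": 4.41, "mu": 4.57, "mu_exp": 3.87,
      "beta_xxx": 79.3, "beta_xyy": 19.5, "beta_xzz": 5.7,
      "beta_zxx": -106.5, "beta_zyy": -36.5, "beta_zzz": 78.2,
      "beta_x": 104.6, "beta_z": -64.8, "beta_vec": 123.0
    },
    "water": {
      "mu_x": 1.88, "mu_z": 5.96, "mu": 6.25,
      "beta_xxx": 183.9, "beta_xyy": 44.0, "beta_xzz": 24.6,
      "beta_zxx": -240.5, "beta_zyy": -56.4, "beta_zzz": 262.3,
      "beta_x": 252.5, "beta_z": -34.6, "beta_vec": 254.9
    }
  },
  "table2": {
    "gas": {
      "modes": [
        {"index": 4,  "wavenumber": 411,  "I_IR": 20,   "A_Raman": 1,   "label": "tau ring",            "beta_vec": 11.5},
        {"index": 5,  "wavenumber": 524,  "I_IR": 22,   "A_Raman": 2,   "label": "delta ring",          "beta_vec": 13.8},
        {"index": 11, "wavenumber": 783,  "I_IR": 4,    "A_Raman": 22,  "label": "delta ring",          "beta_vec": 10.6},
        {"index": 23, "wavenumber": 1523, "I_IR": 127,  "A_Raman": 11,  "label": "nu ring + delta N-H", "beta_vec": 12.5},
        {"index": 24, "wavenumber": 1711, "I_IR": 56,   "A_Raman": 30,  "label": "nu ring + delta C-H", "beta_vec": 10.4},
        {"index": 25, "wavenumber": 1802, "I_IR": 902,  "A_Raman": 58,  "label": "nu C=O + delta N-H",  "beta_vec": 57.8},
        {"index": 26, "wavenumber": 1828, "I_IR": 607,  "A_Raman": 29,  "label": "nu C=O + delta N-H",  "beta_vec": 32.4}
      ],
      "total_beta_v": 65.0,
      "beta_e_eope": 139.8
    },
    "water": {
      "modes": [
        {"index": 5,  "wavenumber": 530,  "I_IR": 45,   "A_Raman": 4,   "label": "delta ring",          "beta_vec": 29.5},
        {"index": 23, "wavenumber": 1527, "I_IR": 236,  "A_Raman": 42,  "label": "nu ring + delta N-H", "beta_vec": 35.6},
        {"index": 24, "wavenumber": 1699, "I_IR": 159,  "A_Raman": 75,  "label": "nu ring + delta C-H", "beta_vec": 29.6},
        {"index": 25, "wavenumber": 1721, "I_IR": 2086, "A_Raman": 115, "label": "nu C=O + delta N-H",  "beta_vec": 127.2},
        {"index": 26, "wavenumber": 1769, "I_IR": 877,  "A_Raman": 116, "label": "nu C=O + delta N-H",  "beta_vec": 70.9}
      ],
      "total_beta_v": 193.9,
      "beta_e_eope": 214.1
    }
  },
  "claims": {
    "hw_max": 0.06563,
    "static_beta_increase_pct": 110,
    "mu_increase_quoted_D": 1.4,
    "mu_increase_pct": 37,
    "dispersion_gas_eope_pct": 13.7,
    "dispersion_gas_shg_pct": 61.5,
    "dispersion_water_eope_pct": -16.0,
    "dispersion_water_shg_pct": 15.5,
    "solvent_ratio_static": 2.1,
    "solvent_ratio_eope": 1.53,
    "solvent_ratio_shg": 1.48,
    "ratio_beta_xxx_water_gas": 2.3,
    "vib_electronic_ratio_gas": 0.46,
    "vib_electronic_ratio_water": 0.91,
    "nu25_share_gas_pct": 89,
    "nu26_share_gas_pct": 50,
    "nu25_solvation_increment": 69.4,
    "nu26_solvation_increment": 38.5,
    "shg_eope_crossing_hw_water": 0.045,
    "lorentz_fwhm_cm1": 10
  }
}
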