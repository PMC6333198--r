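{
  "version": "1.0",
  "notes": "Beam-quality correction factors for an Al2O3:C point dosimeter on a GE Discovery CT750 HD (medium bowtie). Values are scanner-spectrum dependent: scanners with a softer spectrum (e.g. some Toshiba models) need their own table. k_Q uncertainties below are configuration defaults, not measured constants.",
  "by_energy": {
    "condition": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11],
    "kvp": [80, 80, 120, 120, 120, 140, 140, 120, 120, 140, 140],
    "energy_keV": [45.4, 47.9, 51.7, 54.7, 55.3, 58.1, 58.7, 59.5, 60.7, 63.2, 64.9],
    "ct_air": [0.82, 0.85, 0.88, 0.91, 0.93, 0.97, 0.96, 1.00, 1.02, 1.06, 1.09],
    "megavoltage": [0.29, 0.30, 0.31, 0.33, 0.33, 0.35, 0.34, 0.36, 0.36, 0.38, 0.39]
  },
  "by_kvp_position": {
    "ct_air": {
      "kvp": [80, 120, 140],
      "surface": [0.85, 1.03, 1.10],
      "periphery": [0.83, 0.98, 1.03],
      "center": [0.81, 0.90, 0.94]
    },
    "megavoltage": {
      "kvp": [80, 120, 140],
      "surface": [0.30, 0.37, 0.39],
      "periphery": [0.30, 0.35, 0.37],
      "center": [0.29, 0.33, 0.34]
    }
  },
  "vendor_kq": 1.19,
  "k_G": {"vendor": 1.0, "ct_air": 1.0, "megavoltage": 1.03},
  "rel_2sigma": {
    "kq_vendor": 12.4,
    "kq_ct_air": 6.2,
    "kq_megavoltage": 8.2,
    "k_G": 1.0,
    "k_L": 0.0,
    "k_F": 0.0,
    "k_theta": 0.0
  }
}
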