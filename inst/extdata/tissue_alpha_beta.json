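{
  "description": "Organ-specific photon (alpha/beta)x ratios in Gy with 95% confidence intervals, as used for proton CSI organs at risk (heart/thyroid: generic late-effects value; brainstem: CNS late effects; lungs: radiation pneumonitis endpoint).",
  "tissues": {
    "heart":     {"alpha_beta": 3.0, "ci": [1.5, 4.5]},
    "brainstem": {"alpha_beta": 2.1, "ci": [1.1, 3.2]},
    "lungs":     {"alpha_beta": 4.0, "ci": [2.0, 6.0]},
    "thyroid":   {"alpha_beta": 3.0, "ci": [1.5, 4.5]},
    "default":   {"alpha_beta": 3.0, "ci": [1.5, 4.5]}
  }
}
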