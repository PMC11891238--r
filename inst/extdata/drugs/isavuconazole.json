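{
  "name": "isavuconazole",
  "parameters": {
    "ka": 1.51, "V1": 70.36, "k12": 0.30, "k21": 0.100,
    "CLint_h": 254.19, "CLr": 0.003, "FaFg": 0.98,
    "fu_b": 0.01, "MW": 437.47, "Qh": 96.6, "Fa": 1.0,
    "fm_CYP3A4": null
  },
  "units": {
    "ka": "1/h", "V1": "L", "k12": "1/h", "k21": "1/h",
    "CLint_h": "L/h", "CLr": "L/h", "FaFg": "-", "fu_b": "-",
    "MW": "g/mol", "Qh": "L/h", "Fa": "-"
  },
  "source": {
    "ka": "published-fit", "V1": "published-fit", "k12": "published-fit",
    "k21": "published-fit", "CLint_h": "published-fit",
    "CLr": "published-fit", "FaFg": "published-fit",
    "fu_b": "packaged-literature (protein binding >99%)",
    "MW": "packaged-literature", "Qh": "standard-physiology",
    "Fa": "design-decision (Fa = 1, Fg = FaFg)",
    "Ki_CYP3A4_uM": "published (in vitro, recombinant CYP3A4)"
  },
  "Ki_CYP3A4_uM": 5.48
}
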