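{
  "name": "cyclosporine",
  "parameters": {
    "ka": 1.0, "V1": 40.0, "k12": 0.35, "k21": 0.08,
    "CLint_h": 569.8, "CLr": 0.1, "FaFg": 0.28,
    "fu_b": 0.05, "MW": 1202.61, "Qh": 96.6, "Fa": 1.0,
    "fm_CYP3A4": 0.71
  },
  "units": {
    "ka": "1/h", "V1": "L", "k12": "1/h", "k21": "1/h",
    "CLint_h": "L/h", "CLr": "L/h", "FaFg": "-", "fu_b": "-",
    "MW": "g/mol", "Qh": "L/h", "Fa": "-", "fm_CYP3A4": "-"
  },
  "source": {
    "ka": "synthetic-literature-informed",
    "V1": "synthetic-literature-informed",
    "k12": "synthetic-literature-informed",
    "k21": "synthetic-literature-informed",
    "CLint_h": "synthetic-literature-informed (blood CL ~22 L/h)",
    "CLr": "synthetic-literature-informed (renal elimination <1%)",
    "FaFg": "published-hard-constraint (0.28)",
    "fu_b": "packaged-literature",
    "MW": "packaged-literature",
    "Qh": "standard-physiology",
    "Fa": "design-decision (Fa = 1, Fg = FaFg)",
    "fm_CYP3A4": "packaged-literature"
  },
  "Ki_CYP3A4_uM": null
}
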