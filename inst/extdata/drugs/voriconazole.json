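{
  "name": "voriconazole",
  "parameters": {
    "ka": 1.1, "V1": 60.0, "k12": 0.40, "k21": 0.15,
    "CLint_h": 5.1108, "CLr": 0.02, "FaFg": 0.96,
    "fu_b": 0.42, "MW": 349.31, "Qh": 96.6, "Fa": 1.0,
    "fm_CYP3A4": null
  },
  "units": {
    "ka": "1/h", "V1": "L", "k12": "1/h", "k21": "1/h",
    "CLint_h": "L/h", "CLr": "L/h", "FaFg": "-", "fu_b": "-",
    "MW": "g/mol", "Qh": "L/h", "Fa": "-"
  },
  "source": {
    "ka": "synthetic-literature-informed",
    "V1": "synthetic-literature-informed",
    "k12": "synthetic-literature-informed",
    "k21": "synthetic-literature-informed",
    "CLint_h": "calibrated (steady-state trough 1.0 ug/mL at 30 mg BID)",
    "CLr": "synthetic-literature-informed",
    "FaFg": "packaged-literature (high oral bioavailability)",
    "fu_b": "packaged-literature (plasma protein binding ~58%)",
    "MW": "packaged-literature",
    "Qh": "standard-physiology",
    "Fa": "design-decision (Fa = 1, Fg = FaFg)",
    "Ki_CYP3A4_uM": "packaged-literature (in vitro competitive)"
  },
  "Ki_CYP3A4_uM": 2.97
}
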