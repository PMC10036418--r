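[
  {"label": "sim11", "base": "imipramine", "mode": "steady", "overrides": {}},
  {"label": "sim12", "base": "imipramine", "mode": "steady", "overrides": {"k1": 72, "k7": 252}},
  {"label": "sim13", "base": "imipramine", "mode": "steady", "overrides": {"AF": 600000, "GT0": 70000}},
  {"label": "sim14", "base": "imipramine", "mode": "steady", "overrides": {"k1": 54000, "k2": 0.6}},
  {"label": "sim15", "base": "imipramine", "mode": "steady", "overrides": {"k1": 540, "k2": 0.006}},
  {"label": "sim16", "base": "imipramine", "mode": "steady", "overrides": {"k1": 72, "k3": 150000, "k4": 2100, "k7": 252}},
  {"label": "sim17", "base": "imipramine", "mode": "steady", "overrides": {"k4": 21}},
  {"label": "sim18", "base": "imipramine", "mode": "steady", "overrides": {"k9": 6}},
  {"label": "sim19", "base": "imipramine", "mode": "steady", "overrides": {"k9": 6, "k10": 6}},
  {"label": "sim20", "base": "imipramine", "mode": "steady", "overrides": {"k4": 21, "k9": 6}}
]
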