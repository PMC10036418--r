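[
  {"label": "sim1", "base": "propranolol", "mode": "steady", "overrides": {}},
  {"label": "sim2", "base": "propranolol", "mode": "steady", "overrides": {"k1": 198}},
  {"label": "sim3", "base": "propranolol", "mode": "steady", "overrides": {"AF": 600000, "GT0": 70000}},
  {"label": "sim4", "base": "propranolol", "mode": "steady", "overrides": {"k1": 11400, "k2": 0.6}},
  {"label": "sim5", "base": "propranolol", "mode": "steady", "overrides": {"k1": 114, "k2": 0.006}},
  {"label": "sim6", "base": "propranolol", "mode": "steady", "overrides": {"k1": 198, "k3": 66600, "k4": 940}},
  {"label": "sim7", "base": "propranolol", "mode": "steady", "overrides": {"k4": 9.4}},
  {"label": "sim8", "base": "propranolol", "mode": "steady", "overrides": {"k9": 6}},
  {"label": "sim9", "base": "propranolol", "mode": "steady", "overrides": {"k9": 6, "k10": 6}},
  {"label": "sim10", "base": "propranolol", "mode": "steady", "overrides": {"k4": 9.4, "k9": 6}},
  {"label": "PT1000", "base": "propranolol", "mode": "steady", "overrides": {"PT": 1000}},
  {"label": "PT500", "base": "propranolol", "mode": "steady", "overrides": {"PT": 500}},
  {"label": "k5x10", "base": "propranolol", "mode": "steady", "overrides": {"k5": 0.06}},
  {"label": "k5d10", "base": "propranolol", "mode": "steady", "overrides": {"k5": 0.0006}},
  {"label": "sim30", "base": "propranolol", "mode": "steady", "overrides": {"AF": 0, "GT0": 0}}
]
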