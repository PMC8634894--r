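{
  "metadata": {
    "name": "delayed_switch",
    "target_predicate": "T >= 60",
    "description": "reach 'T >= 60' by clamping IGF=100: impossible immediately (blocker B latches via the fast PRE transient), possible at later event indices while the slow GATE is still up, impossible again once GATE has decayed"
  },
  "nodes": [
    {
      "name": "PRE",
      "levels": 100,
      "initial": 100,
      "reaction_class": "fast"
    },
    {
      "name": "GATE",
      "levels": 100,
      "initial": 0,
      "reaction_class": "fast"
    },
    {
      "name": "IGF",
      "levels": 100,
      "initial": 0,
      "reaction_class": "fast"
    },
    {
      "name": "B",
      "levels": 100,
      "initial": 0,
      "reaction_class": "fast"
    },
    {
      "name": "T",
      "levels": 100,
      "initial": 0,
      "reaction_class": "fast"
    }
  ],
  "edges": [
    {
      "regulators": [
        "PRE"
      ],
      "target": "PRE",
      "sign": "inhibition",
      "scenario": 1,
      "k": 1
    },
    {
      "regulators": [
        "PRE"
      ],
      "target": "GATE",
      "sign": "activation",
      "scenario": 1,
      "k": 1
    },
    {
      "regulators": [
        "GATE"
      ],
      "target": "GATE",
      "sign": "inhibition",
      "scenario": 1,
      "k": 0.1
    },
    {
      "regulators": [
        "IGF",
        "PRE"
      ],
      "target": "B",
      "sign": "activation",
      "scenario": 3,
      "k": 3
    },
    {
      "regulators": [
        "B",
        "B"
      ],
      "target": "B",
      "sign": "activation",
      "scenario": 3,
      "k": 2
    },
    {
      "regulators": [
        "B"
      ],
      "target": "B",
      "sign": "inhibition",
      "scenario": 1,
      "k": 1
    },
    {
      "regulators": [
        "IGF",
        "GATE"
      ],
      "target": "T",
      "sign": "activation",
      "scenario": 3,
      "k": 1.5
    },
    {
      "regulators": [
        "T",
        "T"
      ],
      "target": "T",
      "sign": "activation",
      "scenario": 3,
      "k": 2
    },
    {
      "regulators": [
        "B"
      ],
      "target": "T",
      "sign": "inhibition",
      "scenario": 1,
      "k": 3
    },
    {
      "regulators": [
        "T"
      ],
      "target": "T",
      "sign": "inhibition",
      "scenario": 1,
      "k": 1
    }
  ]
}
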