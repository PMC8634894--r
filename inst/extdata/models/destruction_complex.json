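{
  "metadata": {
    "name": "destruction_complex",
    "description": "dummy-node subnetwork: DC_canonical settles at 1-Dsh, DC_degradation saturates at min(1.5-ERK, 1), their scenario-3 product drives DC"
  },
  "nodes": [
    {
      "name": "Dsh",
      "levels": 100,
      "initial": 0,
      "reaction_class": "fast"
    },
    {
      "name": "ERK",
      "levels": 100,
      "initial": 0,
      "reaction_class": "fast"
    },
    {
      "name": "DC_dummy",
      "levels": 100,
      "initial": 0,
      "reaction_class": "fast",
      "clamp": 100
    },
    {
      "name": "DC_canonical",
      "levels": 100,
      "initial": 0,
      "reaction_class": "fast"
    },
    {
      "name": "DC_degradation",
      "levels": 100,
      "initial": 0,
      "reaction_class": "fast"
    },
    {
      "name": "DC",
      "levels": 100,
      "initial": 0,
      "reaction_class": "fast"
    }
  ],
  "edges": [
    {
      "regulators": [
        "DC_dummy"
      ],
      "target": "DC_canonical",
      "sign": "activation",
      "scenario": 1,
      "k": 1
    },
    {
      "regulators": [
        "Dsh"
      ],
      "target": "DC_canonical",
      "sign": "inhibition",
      "scenario": 1,
      "k": 1
    },
    {
      "regulators": [
        "DC_canonical"
      ],
      "target": "DC_canonical",
      "sign": "inhibition",
      "scenario": 1,
      "k": 1
    },
    {
      "regulators": [
        "DC_dummy"
      ],
      "target": "DC_degradation",
      "sign": "activation",
      "scenario": 1,
      "k": 1.5
    },
    {
      "regulators": [
        "ERK"
      ],
      "target": "DC_degradation",
      "sign": "inhibition",
      "scenario": 1,
      "k": 1
    },
    {
      "regulators": [
        "DC_degradation"
      ],
      "target": "DC_degradation",
      "sign": "inhibition",
      "scenario": 1,
      "k": 1
    },
    {
      "regulators": [
        "DC_canonical",
        "DC_degradation"
      ],
      "target": "DC",
      "sign": "activation",
      "scenario": 3,
      "k": 1
    },
    {
      "regulators": [
        "DC"
      ],
      "target": "DC",
      "sign": "inhibition",
      "scenario": 1,
      "k": 1
    }
  ]
}
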