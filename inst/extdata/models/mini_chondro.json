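{
  "metadata": {
    "name": "mini_chondro",
    "description": "synthetic tri-stable mutual-inhibition network: masters X/Y sustained by cooperative feedback through branch activators AX/AY, ignited by decaying signal nodes, read out by downstream markers; attractors X+, Y+ and Null"
  },
  "nodes": [
    {
      "name": "X",
      "levels": 100,
      "initial": 0,
      "reaction_class": "fast"
    },
    {
      "name": "Y",
      "levels": 100,
      "initial": 0,
      "reaction_class": "fast"
    },
    {
      "name": "AX",
      "levels": 100,
      "initial": 0,
      "reaction_class": "fast"
    },
    {
      "name": "AY",
      "levels": 100,
      "initial": 0,
      "reaction_class": "fast"
    },
    {
      "name": "SX1",
      "levels": 100,
      "initial": 0,
      "reaction_class": "slow"
    },
    {
      "name": "SX2",
      "levels": 100,
      "initial": 0,
      "reaction_class": "slow"
    },
    {
      "name": "SY1",
      "levels": 100,
      "initial": 0,
      "reaction_class": "slow"
    },
    {
      "name": "SY2",
      "levels": 100,
      "initial": 0,
      "reaction_class": "slow"
    },
    {
      "name": "MX",
      "levels": 100,
      "initial": 0,
      "reaction_class": "slow"
    },
    {
      "name": "MY",
      "levels": 100,
      "initial": 0,
      "reaction_class": "slow"
    },
    {
      "name": "CX",
      "levels": 100,
      "initial": 0,
      "reaction_class": "slow"
    },
    {
      "name": "CY",
      "levels": 100,
      "initial": 0,
      "reaction_class": "slow"
    }
  ],
  "edges": [
    {
      "regulators": [
        "AX",
        "X"
      ],
      "target": "X",
      "sign": "activation",
      "scenario": 3,
      "k": 1.6
    },
    {
      "regulators": [
        "AX"
      ],
      "target": "X",
      "sign": "activation",
      "scenario": 1,
      "k": 0.2
    },
    {
      "regulators": [
        "Y"
      ],
      "target": "X",
      "sign": "inhibition",
      "scenario": 1,
      "k": 4
    },
    {
      "regulators": [
        "X"
      ],
      "target": "X",
      "sign": "inhibition",
      "scenario": 1,
      "k": 1
    },
    {
      "regulators": [
        "X"
      ],
      "target": "AX",
      "sign": "activation",
      "scenario": 1,
      "k": 1
    },
    {
      "regulators": [
        "SX1"
      ],
      "target": "AX",
      "sign": "activation",
      "scenario": 1,
      "k": 0.25
    },
    {
      "regulators": [
        "SX2"
      ],
      "target": "AX",
      "sign": "activation",
      "scenario": 1,
      "k": 0.25
    },
    {
      "regulators": [
        "AX"
      ],
      "target": "AX",
      "sign": "inhibition",
      "scenario": 1,
      "k": 1
    },
    {
      "regulators": [
        "SX1"
      ],
      "target": "SX1",
      "sign": "inhibition",
      "scenario": 1,
      "k": 0.1
    },
    {
      "regulators": [
        "SX2"
      ],
      "target": "SX2",
      "sign": "inhibition",
      "scenario": 1,
      "k": 0.1
    },
    {
      "regulators": [
        "X"
      ],
      "target": "MX",
      "sign": "activation",
      "scenario": 1,
      "k": 1
    },
    {
      "regulators": [
        "MX"
      ],
      "target": "MX",
      "sign": "inhibition",
      "scenario": 1,
      "k": 0.1
    },
    {
      "regulators": [
        "MX"
      ],
      "target": "CX",
      "sign": "activation",
      "scenario": 1,
      "k": 0.5
    },
    {
      "regulators": [
        "CX"
      ],
      "target": "CX",
      "sign": "inhibition",
      "scenario": 1,
      "k": 0.1
    },
    {
      "regulators": [
        "AY",
        "Y"
      ],
      "target": "Y",
      "sign": "activation",
      "scenario": 3,
      "k": 1.6
    },
    {
      "regulators": [
        "AY"
      ],
      "target": "Y",
      "sign": "activation",
      "scenario": 1,
      "k": 0.2
    },
    {
      "regulators": [
        "X"
      ],
      "target": "Y",
      "sign": "inhibition",
      "scenario": 1,
      "k": 4
    },
    {
      "regulators": [
        "Y"
      ],
      "target": "Y",
      "sign": "inhibition",
      "scenario": 1,
      "k": 1
    },
    {
      "regulators": [
        "Y"
      ],
      "target": "AY",
      "sign": "activation",
      "scenario": 1,
      "k": 1
    },
    {
      "regulators": [
        "SY1"
      ],
      "target": "AY",
      "sign": "activation",
      "scenario": 1,
      "k": 0.25
    },
    {
      "regulators": [
        "SY2"
      ],
      "target": "AY",
      "sign": "activation",
      "scenario": 1,
      "k": 0.25
    },
    {
      "regulators": [
        "AY"
      ],
      "target": "AY",
      "sign": "inhibition",
      "scenario": 1,
      "k": 1
    },
    {
      "regulators": [
        "SY1"
      ],
      "target": "SY1",
      "sign": "inhibition",
      "scenario": 1,
      "k": 0.1
    },
    {
      "regulators": [
        "SY2"
      ],
      "target": "SY2",
      "sign": "inhibition",
      "scenario": 1,
      "k": 0.1
    },
    {
      "regulators": [
        "Y"
      ],
      "target": "MY",
      "sign": "activation",
      "scenario": 1,
      "k": 1
    },
    {
      "regulators": [
        "MY"
      ],
      "target": "MY",
      "sign": "inhibition",
      "scenario": 1,
      "k": 0.1
    },
    {
      "regulators": [
        "MY"
      ],
      "target": "CY",
      "sign": "activation",
      "scenario": 1,
      "k": 0.5
    },
    {
      "regulators": [
        "CY"
      ],
      "target": "CY",
      "sign": "inhibition",
      "scenario": 1,
      "k": 0.1
    }
  ]
}
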