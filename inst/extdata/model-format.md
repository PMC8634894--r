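# Activity-network model file format

A model file is a single JSON document:

```json
{
  "metadata": { "name": "example", "...": "free-form key/value" },
  "nodes": [
    { "name": "A", "levels": 100, "initial": 0,
      "reaction_class": "fast", "clamp": 100 }
  ],
  "edges": [
    { "regulators": ["A"], "target": "B", "sign": "activation",
      "scenario": 1, "k": 0.5 },
    { "regulators": ["A", "B"], "target": "C", "sign": "activation",
      "scenario": 3, "k": 1.0 }
  ]
}
```

## nodes

| field            | type    | default | meaning                                             |
|------------------|---------|---------|-----------------------------------------------------|
| `name`           | string  | required| unique identifier                                   |
| `levels`         | int >=1 | 100     | activity granularity; activities live in [0, levels]|
| `initial`        | int     | 0       | initial activity, in [0, levels]                    |
| `clamp`          | int     | absent  | hold the node constant at this level (dummy node, knockout = 0, constitutive activation = levels) |
| `reaction_class` | string  | "fast"  | "slow" (gene expression, k scale 0.1) or "fast" (post-translational, k scale 1.0) |

## edges

| field        | type          | default      | meaning                                   |
|--------------|---------------|--------------|-------------------------------------------|
| `regulators` | array of 1-2  | required     | regulator node names; exactly 2 iff scenario 3 |
| `target`     | string        | required     | target node name                          |
| `sign`       | string        | "activation" | "activation" or "inhibition"              |
| `scenario`   | 1, 2 or 3     | 1            | rate law (below)                          |
| `k`          | number > 0    | 1.0          | interaction strength                      |

With activities normalised to `a = level / levels`:

- scenario 1: `R = k * a[E]`
- scenario 2: `R = k * a[E] * avail(S)` where `avail(S)` is the target's
  inactive fraction `1 - a[S]` for activations and its active fraction
  `a[S]` for inhibitions
- scenario 3: `R = k * a[E1] * a[E2]` (AND kinetics)

Sign and scenario are explicit fields and never inferred from `k`.
A translated model carries exactly one self-inhibition edge (scenario 1,
sign inhibition, regulator = target) per non-constant node.
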