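columns:
- column: UL
  type: dot-color
  levels:
  - red
  - green
- column: LL
  type: dot-color
  levels:
  - red
  - green
- column: R
  type: dot-color
  levels:
  - green
  - red
patterns:
- pattern: 1
  levels:
    UL: red
    LL: red
    R: green
- pattern: 2
  levels:
    UL: green
    LL: green
    R: red
features:
  level_feature: yes
  coordinates:
  - column: UL
    x: 0.0
    'y': 1.0
  - column: LL
    x: 0.0
    'y': 0.0
  - column: R
    x: 0.866025403784439
    'y': 0.5
node_order:
- node: 1
  column: UL
  level: red
- node: 2
  column: UL
  level: green
- node: 3
  column: LL
  level: red
- node: 4
  column: LL
  level: green
- node: 5
  column: R
  level: green
- node: 6
  column: R
  level: red
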