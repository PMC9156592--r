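network:
  shared_resistances:
    R0: 1.0
    R1: 1.0
    R2: 2.0
    R3: 1.0
  topology:
  - from: AO
    to: n1
    r: R0
  - from: n1
    to: n2
    r: R1
  - from: n2
    to: n3
    r: R2
  - from: n3
    to: n4
    r: R3
  - from: n1
    to: A
  - from: n2
    to: B
  - from: n3
    to: C
  - from: n4
    to: D
  - from: n4
    to: E
  compartments:
  - label: A
    r: 1.0
    c: 0.0800000000000000016653
    v_rest: 1.0
  - label: B
    r: 15.0
    c: 0.0599999999999999977796
    v_rest: 1.0
  - label: C
    r: 11.0
    c: 0.0500000000000000027756
    v_rest: 1.0
  - label: D
    r: 15.0
    c: 0.0200000000000000004163
    v_rest: 1.0
  - label: E
    r: 7.0
    c: 0.0200000000000000004163
    v_rest: 1.0
ventilator:
  mode: CF
  peep: 2.0
  ti: 1.0
  ttot: 3.0
  q_aw: 1.6999999999999999555911

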