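- item_id: item_01
  type: threshold
  description: synthetic mobility item 1 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_02
  type: threshold
  description: synthetic adl item 2 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_03
  type: threshold
  description: synthetic iadl item 3 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_04
  type: map
  description: synthetic chronic item 4 (categorical)
  map:
    none: 0.0
    mild: 0.5
    severe: 1.0
- item_id: item_05
  type: threshold
  description: synthetic sensory item 5 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_06
  type: threshold
  description: synthetic mood item 6 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_07
  type: threshold
  description: synthetic strength item 7 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_08
  type: map
  description: synthetic cognition item 8 (categorical)
  map:
    none: 0.0
    mild: 0.5
    severe: 1.0
- item_id: item_09
  type: threshold
  description: synthetic mobility item 9 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_10
  type: threshold
  description: synthetic adl item 10 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_11
  type: threshold
  description: synthetic iadl item 11 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_12
  type: map
  description: synthetic chronic item 12 (categorical)
  map:
    none: 0.0
    mild: 0.5
    severe: 1.0
- item_id: item_13
  type: threshold
  description: synthetic sensory item 13 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_14
  type: threshold
  description: synthetic mood item 14 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_15
  type: threshold
  description: synthetic strength item 15 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_16
  type: map
  description: synthetic cognition item 16 (categorical)
  map:
    none: 0.0
    mild: 0.5
    severe: 1.0
- item_id: item_17
  type: threshold
  description: synthetic mobility item 17 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_18
  type: threshold
  description: synthetic adl item 18 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_19
  type: threshold
  description: synthetic iadl item 19 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_20
  type: map
  description: synthetic chronic item 20 (categorical)
  map:
    none: 0.0
    mild: 0.5
    severe: 1.0
- item_id: item_21
  type: threshold
  description: synthetic sensory item 21 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_22
  type: threshold
  description: synthetic mood item 22 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_23
  type: threshold
  description: synthetic strength item 23 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_24
  type: map
  description: synthetic cognition item 24 (categorical)
  map:
    none: 0.0
    mild: 0.5
    severe: 1.0
- item_id: item_25
  type: threshold
  description: synthetic mobility item 25 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_26
  type: threshold
  description: synthetic adl item 26 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_27
  type: threshold
  description: synthetic iadl item 27 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_28
  type: map
  description: synthetic chronic item 28 (categorical)
  map:
    none: 0.0
    mild: 0.5
    severe: 1.0
- item_id: item_29
  type: threshold
  description: synthetic sensory item 29 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_30
  type: threshold
  description: synthetic mood item 30 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_31
  type: threshold
  description: synthetic strength item 31 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_32
  type: map
  description: synthetic cognition item 32 (categorical)
  map:
    none: 0.0
    mild: 0.5
    severe: 1.0
- item_id: item_33
  type: threshold
  description: synthetic mobility item 33 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_34
  type: threshold
  description: synthetic adl item 34 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_35
  type: threshold
  description: synthetic iadl item 35 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_36
  type: map
  description: synthetic chronic item 36 (categorical)
  map:
    none: 0.0
    mild: 0.5
    severe: 1.0
- item_id: item_37
  type: threshold
  description: synthetic sensory item 37 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_38
  type: threshold
  description: synthetic mood item 38 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_39
  type: threshold
  description: synthetic strength item 39 (binary cutoff)
  cutoff: 1.0
  direction: ge
- item_id: item_40
  type: map
  description: synthetic cognition item 40 (categorical)
  map:
    none: 0.0
    mild: 0.5
    severe: 1.0
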