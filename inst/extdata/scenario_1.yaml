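name: "Scenario 1: initial stabilization"
infusate: whole_blood
seed: 1
phases:
  - name: initial_hemorrhage
    internal_hemorrhage: 500
    stop_hemorrhage_at_end: true
    until: {map_le: 75}
  - name: extremity_bleed_tourniquet
    open_extremity_valve: true
    start_sacm: true
    until: {event: atkt_engaged}
  - name: initial_resuscitation
    until: {event: arc_completed}
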