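name: "Scenario 4: loosening then internal hemorrhage"
infusate: whole_blood
seed: 4
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
  - name: loosen_tourniquet
    delay: 10
    loosen_tourniquet: 0.55
    until: {event: atkt_reengaged}
  - name: internal_hemorrhage
    delay: 10
    internal_hemorrhage: 240
    stop_hemorrhage_at_end: true
    until: {event: arc_completed}
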