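name: overfill_injection
steps:
  - step: comment
    text: "overfill injection: 1700 nL sample + 3000 nL solvent A chase"
  - step: valve_two_position
    position: A
  - step: valve_selector
    port: 6
  - step: punch_foil
    labware: sample_plate
    well: B2
  - step: move_to_well
    labware: sample_plate
    well: B2
    tool: needle
  - step: aspirate
    volume: 1700 nL
    label: sample
  - step: move_to_well
    labware: solvent_reservoir
    well: A1
    tool: needle
  - step: aspirate
    volume: 3000 nL
  - step: valve_two_position
    position: B
  - step: pulse_relay
    duration: 0.5
  - step: wait_input
    pin: 7
    level: 1
    timeout: 3300
  - step: valve_two_position
    position: A
  - step: dispense
    volume: 4700 nL
  - step: comment
    text: "injection complete; flush the loop before the next sample"
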