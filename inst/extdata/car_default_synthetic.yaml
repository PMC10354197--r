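sprung_mass: 1500.0
inertia_pitch: 2160.0
inertia_roll: 460.0
a_front: 1.2
b_rear: 1.5
half_track_front: 0.75
half_track_rear: 0.75
k_susp:
- 30000.0
- 30000.0
- 28000.0
- 28000.0
c_susp:
- 2500.0
- 2500.0
- 2200.0
- 2200.0
unsprung_mass:
- 40.0
- 40.0
- 45.0
- 45.0
k_tire:
- 200000.0
- 200000.0
- 200000.0
- 200000.0
c_tire:
- 0.0
- 0.0
- 0.0
- 0.0
seat_x: -0.3
seat_y: 0.0
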