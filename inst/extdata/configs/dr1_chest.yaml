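# Flat-panel DR system 1 (CsI, 143 um pitch), chest protocol, AEC.
system_id: DR1
protocol: chest
tube_voltage_kV: 133
sid_cm: 250
sdd_cm: 200
tube_load_mAs: 1.6
filtration: 1/0.2
beam_mode: cone
pixel_pitch_mm: 0.143
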