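# Flat-panel DR system 2 (CsI, 139 um pitch), chest protocol, AEC.
system_id: DR2
protocol: chest
tube_voltage_kV: 145
sid_cm: 300
sdd_cm: 250
tube_load_mAs: 1.8
filtration: 0/0.2
beam_mode: cone
pixel_pitch_mm: 0.139
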