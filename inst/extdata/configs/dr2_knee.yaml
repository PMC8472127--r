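# Flat-panel DR system 2, knee protocol, manual exposure.
system_id: DR2
protocol: knee
tube_voltage_kV: 63
sid_cm: 115
sdd_cm: 75
tube_load_mAs: 6.3
filtration: 0/0
beam_mode: cone
pixel_pitch_mm: 0.139
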