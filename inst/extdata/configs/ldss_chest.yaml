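# Slot-scanner, chest protocol (scan speed 6). sdd_cm and pixel_pitch_mm
# are example values supplied by the user of this package, not vendor data.
system_id: LDSS
protocol: chest
tube_voltage_kV: 90
sid_cm: 130
sdd_cm: 80
scan_speed: 6
filtration: 0/0.1
beam_mode: slot
pixel_pitch_mm: 0.254
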