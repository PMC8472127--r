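# Slot-scanner, knee protocol (scan speed 8). sdd_cm and pixel_pitch_mm
# are example values supplied by the user of this package, not vendor data.
system_id: LDSS
protocol: knee
tube_voltage_kV: 68
sid_cm: 130
sdd_cm: 80
scan_speed: 8
filtration: 0/0
beam_mode: slot
pixel_pitch_mm: 0.254
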