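# Validation regime 1: DO setpoint ~0.5 mg/L
volume_m3: 20
flow_m3h: 1.8
srt_d: 8
ras_ratio: 2.5
ras_m3h: 4.5
do_mgl: 0.5
temp_c: 26.5
mlss_mgl: 2000
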