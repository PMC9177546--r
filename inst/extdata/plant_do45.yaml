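# Validation regime 2: DO setpoint ~4.5 mg/L
volume_m3: 20
flow_m3h: 1.8
srt_d: 22
ras_ratio: 3.0
ras_m3h: 5.4
do_mgl: 4.5
temp_c: 23
mlss_mgl: 2000
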