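# Calibration regime: DO setpoint 2.5 mg/L
volume_m3: 20
flow_m3h: 1.8
srt_d: 11
ras_ratio: 2.5    # reported ratio; 2.5 x 1.8 = 4.5 m3/h disagrees with the
ras_m3h: 3.7      # reported absolute flow, which is authoritative here
was_m3d: 2.2
do_mgl: 2.5
temp_c: 26
mlss_mgl: 2000
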