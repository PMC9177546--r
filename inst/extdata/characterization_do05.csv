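determinand,phase,value,spread,units
ph,influent,7.2,0.2,-
temperature,influent,26.5,1.5,C
cod,influent,455.6,37.1,mg/L
bod,influent,232.8,29.8,mg/L
tss,influent,316.6,34.7,mg/L
nh3,influent,40.8,7.9,mg/L
tkn,influent,48.6,7.6,mg/L
tn,influent,50.7,8.6,mg/L
cod,effluent,85.0,,mg/L
bod,effluent,46.0,,mg/L
tss,effluent,58.0,,mg/L
nh3,effluent,32.8,14.3,mg/L
tkn,effluent,35.6,,mg/L
tn,effluent,43.6,,mg/L
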