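determinand,phase,value,spread,units
ph,influent,7.0,0.6,-
temperature,influent,26,4,C
cod,influent,627,188,mg/L
bod,influent,306,84,mg/L
tss,influent,384,80,mg/L
nh3,influent,33.7,8.2,mg/L
tkn,influent,44.2,7.1,mg/L
tn,influent,46.7,8.5,mg/L
cod,effluent,62,5,mg/L
bod,effluent,31,,mg/L
tss,effluent,37,,mg/L
nh3,effluent,4.9,1.6,mg/L
tkn,effluent,6.2,,mg/L
tn,effluent,14.0,,mg/L
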