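determinand,phase,value,spread,units
ph,influent,7.2,0.2,-
temperature,influent,23,2.0,C
cod,influent,440.4,25.7,mg/L
bod,influent,221.6,18.4,mg/L
tss,influent,262.9,27.6,mg/L
nh3,influent,34.5,9.6,mg/L
tkn,influent,42.5,9.6,mg/L
tn,influent,45.9,11.6,mg/L
cod,effluent,25.5,,mg/L
bod,effluent,9.0,,mg/L
tss,effluent,15.0,,mg/L
nh3,effluent,0.2,0.2,mg/L
tkn,effluent,1.3,,mg/L
tn,effluent,14.2,,mg/L
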