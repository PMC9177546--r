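code,shape,low,high,source
X52,uniform,0.63,0.69,literature range for aerobic heterotrophic yield
X53,uniform,0.52,0.57,literature range for anoxic heterotrophic yield
X16,uniform,0.23,0.70,literature range for aerobic heterotrophic decay rate
X12,uniform,0.375,0.48,half of total denitrification reduction factor range assuming equal reduction for NO2 and NO3
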