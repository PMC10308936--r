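condition,source,mean_cfu_per_l,sd_cfu_per_l
N2-fixing,detached,2.92e8,3.20e7
N2-fixing,resident,1.42e11,1.36e10
nitrate-fed,detached,2.03e9,2.09e8
nitrate-fed,resident,3.48e11,1.48e10
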