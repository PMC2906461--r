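compound,phase,feed_mM,residual_mM
cellobiose,liquid,2.2,0
acetate,liquid,0,5.93
fumarate,liquid,4.9,0
succinate,liquid,0,3.586
malate,liquid,0,0.044
sulfate,liquid,8,1.9
hydrogen,liquid,0,0
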