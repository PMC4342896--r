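disease,ratio_lo,ratio_hi,extra_marker,extra_lo,extra_hi,printed_sensitivity
DMD,2.9,4.1,PYGM,0.1,0.3,100
BMD,1.9,3.5,GAPDH,0.6,1.2,86
NCL,1.5,2.1,GPD1,0.4,0.6,100
LGMD2C,2.5,3.9,SDH,0.5,0.7,100
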