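# Bacterial: candidate model structure recovered by implicit sparse regression
name: BacterialCM
states: x1 x2
params: p1 p2 p3 p4 p5 p6 p7 p8 p9 p10 p11 p12 p13 p14 p15 p16
dx1/dt = p1 + p2/(p3 + p4*x1^2) + (p5*x2 + p6)/(p7 + p8*x1 + p9*x2)
dx2/dt = p10/(p11 + p12*x1^5) + p13*x2/(p14 + p15*x1 + p16*x2)
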