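# Glycolysis: candidate model structure recovered by implicit sparse regression
name: GlycolysisCM
states: x1 x2 x3 x4 x5 x6 x7
params: p1 p2 p3 p4 p5 p6 p7 p8 p9 p10 p11 p12 p13 p14 p15 p16 p17 p18 p19 p20 p21 p22 p23 p24 p25 p26 p27 p28 p29
dx1/dt = p1 + p2*x1*x6/(p4 + p3*x6^4)
dx2/dt = p5*x2 + p6*x2*x7 + p7*x1*x6/(p8*x6^4 + p9)
dx3/dt = p10*x2 + p11*x3 + p12*x2*x7 + p13*x3*x6
dx4/dt = p14*x3 + p15*x4 + p16*x5 + p17*x3*x6 + p18*x4*x7
dx5/dt = p19*x4 + p20*x5
dx6/dt = p21*x3 + p22*x6*x3 + p23*x6 + p24*x6*x1/(p25 + p26*x6^4)
dx7/dt = p27*x2 + p28*x2*x7 + p29*x4*x7
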