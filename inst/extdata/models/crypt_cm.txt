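# Crypt: candidate model structure recovered by implicit sparse regression
name: CryptCM
states: x1 x2 x3
params: p1 p2 p3 p4 p5 p6 p7 p8 p9 p10 p11 p12 p13 p14 p15 p16 p17 p18 p19 p20 p21
dx1/dt = p1 + p2*x1 + p3/(p5 + x1*p4)
dx2/dt = (p6*x2 + p7*x1 + p8*x1*x2 + p9*x2^2 + p10*x1^2 + p11*x1^2*x2)/(p12 + p13*x1 + p14*x2 + p15*x1*x2)
dx3/dt = p16*x2 + p17*x3 + p18/(p19*x2 + p20) + p21
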