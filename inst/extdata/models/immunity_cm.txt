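# Immunity: candidate model structure recovered by implicit sparse regression
name: ImmunityCM
states: x1 x2
params: p1 p2 p3 p4 p5 p6 p7 p8 p9
dx1/dt = p1*x1 + p2*x1^2 + p3*x1*x2 + p4*x1^3/(p5*x2 + p6*x1)
dx2/dt = p7 + p8*x1 + p9*x2
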