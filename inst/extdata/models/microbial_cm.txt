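# Microbial: candidate model structure recovered by implicit sparse regression
name: MicrobialCM
states: x1 x2
params: p1 p2 p3 p4 p5 p6 p7
dx1/dt = p1*x1 + p2*x1/(p3 + p4*x2)
dx2/dt = p5*x1*x2/(p6 + p7*x2)
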