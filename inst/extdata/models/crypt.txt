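# Colonic crypt cell-renewal model with saturating feedback: ground truth
name: Crypt
states: x1 x2 x3
params: a1 a2 a3 b1 b2 b3 g k0 k1 m0 m1
dx1/dt = (a3 - a1 - a2)*x1 - k0*x1^2/(1 + m0*x1)
dx2/dt = (b3 - b1 - b2)*x2 + a2*x1 - k1*x2^2/(1 + m1*x2) + k0*x1^2/(1 + m0*x1)
dx3/dt = -g*x3 + b2*x2 + k1*x2^2/(1 + m1*x2)
x0: x1=0.4 x2=0.3 x3=0.2
values: a1=0.25 a2=0.35 a3=1.1 b1=0.2 b2=0.3 b3=1.0 g=0.5 k0=0.7 k1=0.6 m0=0.9 m1=1.1
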