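# Lorenz convection system: ground truth
name: Lorenz
states: x1 x2 x3
params: a b c
dx1/dt = a*(x2 - x1)
dx2/dt = x1*(b - x3) - x2
dx3/dt = x1*x2 - c*x3
x0: x1=-8 x2=7 x3=27
values: a=10 b=28 c=8/3
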