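# Yeast glycolytic oscillator (7 metabolite pools): ground truth as used here.
# Parameter values are order-one settings chosen for bounded, non-degenerate
# trajectories; see the package vignette for the rationale.
name: Glycolysis
states: x1 x2 x3 x4 x5 x6 x7
params: c1 c2 c3 d1 d2 d3 d4 e1 e2 e3 e4 f1 f3 f4 f5 g1 g2 h1 h2 h3 h4 h5 j1 j2 j3
dx1/dt = c1 + c2*x1*x6/(1 + c3*x6^4)
dx2/dt = d1*x1*x6/(1 + d2*x6^4) + d3*x2 - d4*x2*x7
dx3/dt = e1*x2 + e2*x3 + e3*x2*x7 + e4*x3*x6
dx4/dt = f1*x3 + e2*x4 + f3*x5 + f4*x3*x6 + f5*x4*x7
dx5/dt = g1*x4 + g2*x5
dx6/dt = h3*x3 + h5*x6 + h4*x3*x6 + h1*x1*x6/(1 + h2*x6^4)
dx7/dt = j1*x2 + j2*x2*x7 + j3*x4*x7
x0: x1=0.5 x2=1 x3=0.4 x4=0.3 x5=0.6 x6=1 x7=0.2
values: c1=0.5 c2=-1 c3=1 d1=1 d2=1 d3=-0.6 d4=0.4 e1=0.8 e2=-0.7 e3=0.3 e4=-0.2 f1=0.6 f3=0.2 f4=0.3 f5=-0.3 g1=0.5 g2=-0.4 h1=-0.8 h2=1 h3=0.6 h4=-0.3 h5=-0.4 j1=0.3 j2=-0.5 j3=0.05
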