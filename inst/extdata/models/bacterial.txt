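# B. subtilis competence circuit (ComK/ComS), dimensionless: ground truth
name: Bacterial
states: x1 x2
params: a1 a2 a3 b1 b2
dx1/dt = a1 + a2*x1^2/(a3 + x1^2) - x1/(1 + x1 + x2)
dx2/dt = b1/(1 + b2*x1^5) - x2/(1 + x1 + x2)
x0: x1=0.6 x2=1.2
values: a1=0.2 a2=0.5 a3=1 b1=1 b2=1
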