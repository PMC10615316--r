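# Batch-reactor microbial growth with Monod kinetics: ground truth
name: Microbial
states: x1 x2
params: mu Ks Kd gamma
dx1/dt = mu*x2*x1/(Ks + x2) - Kd*x1
dx2/dt = -mu*x2*x1/(gamma*(Ks + x2))
x0: x1=0.3 x2=4
values: mu=0.8 Ks=1.5 Kd=0.15 gamma=0.6
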