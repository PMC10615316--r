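# Bacteria / immune-system competition with QSSM modulation: ground truth
name: Immunity
states: x1 x2
params: a k e beta gamma alpha S d delta
dx1/dt = a*(1 - x1/k)*x1 - e*x1*x2 - beta*gamma*x1*x2^2/(gamma*x2 + alpha*x1)
dx2/dt = S + d*x1 - delta*x2
x0: x1=2 x2=0.8
values: a=1.2 k=8 e=0.25 beta=0.9 gamma=1.6 alpha=0.8 S=0.6 d=0.3 delta=0.5
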