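# birth-death process: stationary law Poisson(k/d)
param k = 2
param d = 1
birth: 0 -> A with k
death: A -> 0 with d
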