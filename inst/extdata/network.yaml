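# Reference operating point of the three-neuron master-slave network with a
# dynamic inhibitory loop: intrinsic periods 60/70/80 time units (1 tu = 1 ms)
# and couplings g12 (master -> slave, excitatory), g23 (slave -> interneuron,
# excitatory), g32 (interneuron -> slave, inhibitory).
P1i: 60
P2i: 70
P3i: 80
g12: 0.015
g23: 0.0275
g32: 0.002
run:
  n_cycles: 110
  discard: 20
  phases_n: 50
  seed: 1
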