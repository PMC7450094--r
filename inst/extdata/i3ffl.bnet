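# incoherent feed-forward loop, type 3: input held on, relay x2,
# output x3 requires the relay and the absence of the input
targets, factors
x1, 1
x2, x1
x3, x2 & !x1
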