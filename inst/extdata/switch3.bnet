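# three-component toggle switch: mutual inhibition between x1 and x2,
# x3 activated by x2 and inhibited by x1
targets, factors
x1, !x2
x2, !x1
x3, x2 & !x1
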