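# clock_name: synthetic_identity_clock
# transform: identity
# note: synthetic fixture clock for examples and tests; not a published clock
var,coef
(Intercept),2.5
cg00001,12
cg00002,-8
cg00003,4.5
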