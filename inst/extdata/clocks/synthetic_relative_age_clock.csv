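# clock_name: synthetic_relative_age_clock
# transform: relative_age
# transform_params: L=25,g=0.2
# note: synthetic fixture clock for examples and tests; not a published clock
var,coef
(Intercept),0.1
cg00001,0.6
cg00002,-0.4
cg00003,0.25
cg00004,0.15
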