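# label: French model without latitude
# intercept:              481
# n1: NA
# n0: NA
# note: constant printed parenthesized as (481); stored as printed, sign/format ambiguous
# note: training n1/n0 not published
variable,coefficient,inclusion_order
Alti,         0.02967,6
Prec,       -0.002588,3
HJul,         -0.4211,4
SRad,          -153.6,2
Temp,          0.3106,1
DPre,         0.08299,5
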