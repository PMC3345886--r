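# label: French model with latitude
# intercept:            496.9
# n1: NA
# n0: NA
# note: constant printed parenthesized as (496.9); stored as printed, sign/format ambiguous
# note: inclusion ranks as printed: Prec and Lati both rank 3, no rank 4; kept verbatim, flagged inconsistent
# note: Alti250 kept as printed (altitude at different support than Alti)
# note: training n1/n0 not published
variable,coefficient,inclusion_order
Alti250,         0.00248,1
Prec,       -0.003152,3
SRad,          -43.11,5
DPre,          0.1059,2
Lati,          -8.826,3
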