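event,pt_code,a,b,c,d,printed_ror,printed_ci_low,printed_ci_high
drug-induced liver injury,10072268,3,171,10,9134,16.03,4.37,58.74
thrombotic microangiopathy,10043645,9,165,108,9036,4.57,2.28,9.18
tremor,10044565,5,169,95,9049,2.82,1.13,7.02
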