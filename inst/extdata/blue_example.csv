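# two equal-proportion sets from one population, selected on entry-mean BLUEs
# differing only in heritability (0.36 vs 0.81)
label,pi,mu,sigma_u,criterion,accuracy
P1,0.5,0,1,BLUE,0.36
P2,0.5,0,1,BLUE,0.81
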