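# the same two sets selected on BLUPs with prediction accuracies 0.6 and 0.9
label,pi,mu,sigma_u,criterion,accuracy
P1,0.5,0,1,BLUP,0.6
P2,0.5,0,1,BLUP,0.9
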