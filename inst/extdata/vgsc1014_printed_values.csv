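metric,insecticide,value,digits
group_chisq,DDT,75.2,1
group_chisq,deltamethrin,14.9,1
group_chisq,alpha-cypermethrin,62.6,1
sensitivity_pct,DDT,89.2,1
sensitivity_pct,deltamethrin,76.6,1
sensitivity_pct,alpha-cypermethrin,87.0,1
specificity_pct,DDT,74.7,1
specificity_pct,deltamethrin,58.1,1
specificity_pct,alpha-cypermethrin,86.9,1
tp,DDT,74,0
fp,DDT,21,0
tn,DDT,62,0
fn,DDT,9,0
tp,deltamethrin,36,0
fp,deltamethrin,26,0
tn,deltamethrin,36,0
fn,deltamethrin,11,0
tp,alpha-cypermethrin,20,0
fp,alpha-cypermethrin,18,0
tn,alpha-cypermethrin,119,0
fn,alpha-cypermethrin,3,0
or_ser_vs_leu,DDT,9.35,2
or_phe_vs_ser,DDT,2.79,2
or_ser_vs_leu,deltamethrin,3.47,2
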