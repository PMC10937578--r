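variable,percentContribution,permutationImportance
Bio6,29.8,24.4
Bio12,24.6,0.3
Bio4,19.8,20.6
Slope,7.6,6.4
Bio13,6.4,41.8
T_bs,6.3,1.2
T_cec_clay,3.4,1.4
Bio5,1,1.8
Bio8,0.4,0.9
Bio3,0.3,0.6
T_esp,0.3,0.3
T_cec_soil,0.2,0.3
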