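cancer_type,DT_pt,DT_m,T_pot,d_pt,d_lo,d_hi
breast,210,105,15,2.5,1.4,3
colorectal,175,105,4,4.5,3.5,5.1
headneck,84,56,4,2.8,1.3,4
lung,168,56,2.5,2,1.7,4.1
prostate,392,98,34,1.2,0.1,2.9
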