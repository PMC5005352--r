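sample_id,depth_mbsf,thaa_fmol_per_cell,thaa_c_fmol_per_cell,total_c_fg_published
LD_0.40,0.4,0.18,0.88,19
LD_2.75,2.75,0.29,1.2,26
LD_4.32,4.32,0.28,1.3,29
LD_9.57,9.57,0.31,1.4,31
LD_14.55,14.55,0.21,0.97,21
LD_20.53,20.53,0.13,0.66,14
LD_38.95,38.95,0.17,0.78,17
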