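field_mm,p_housing,p_housing_alt,p_sens,p_vol,k_total,note
3,0.9725,0.973,0.989,1.075,1.033,published simulation values; alt housing value is the rounded variant
4,0.980,NA,NA,1.022,0.998,published housing and volume factors; sensitive-volume factor not reported separately
5,NA,NA,NA,NA,0.988,only the published total correction; components not reported
25,1,1,1,1,1,machine-specific reference field; unity by definition
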