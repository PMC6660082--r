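assay_id,mu_ct,sigma2_between,sigma2_within
miR-122,17.60,1.47,1.49
miR-let7b,14.70,0.05,0.04
miR-17-5p,12.99,0.04,0.03
miR-19b-3p,12.05,0.02,0.03
miR-20a-5p,14.18,0.01,0.01
miR-20b,16.08,0.01,0.01
miR-133a,20.21,0.91,0.99
miR-let7d,18.23,0.21,0.30
miR-106a,11.98,0.04,0.03
miR-125b-5p,20.50,0.22,0.57
miR-130a,18.37,0.11,0.28
miR-16,11.49,0.06,0.07
miR-24,11.91,0.09,0.19
miR-26b,18.94,0.21,0.21
miR-221-3p,15.48,0.23,0.24
miR-375,18.81,0.79,1.02
miR-483-5p,14.74,0.47,0.25
miR-92a,12.74,0.15,0.10
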