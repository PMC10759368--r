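age_min,age_max,ravlt_mean,ravlt_sd,tmtb_mean,tmtb_sd
55,65,8.5,2.8,95,40
65,75,7.8,2.8,110,40
75,90,7.0,2.8,130,40
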