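"region_label","sex","age_group","per_capita_mean","per_capita_se","recorded_mean","recorded_se","unrecorded_mean","p_abstainer","p_former","effective_n","coverage_factor"
"Asia, Pacific (high income)","male","15-34",13.51,1.57,,,,0.05,0.07,1000,0.8
"Asia, Central","male","15-34",10.62,1.73,,,,0.23,0.13,1000,0.8
"Asia, East","male","15-34",9.88,1.42,,,,0.13,0.15,1000,0.8
"Asia, South","male","15-34",3.8,0.8,,,,0.73,0.11,1000,0.8
"Asia, Southeast","male","15-34",5.21,0.79,,,,0.56,0.17,1000,0.8
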