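region,n_surveys,n_children,sam_all_pct,mam_all_pct,excluded_sam_pct,underestimated_sam_pct,ignored_risk_sam_pct,correctly_detected_sam_pct,excluded_mam_pct,mam_in_program_pct,rutf_allocation_increase
Overall,550,400138,3.7,12.3,25.8,19.6,16.7,37.9,49.6,69.6,2.44
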