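region,n_surveys,n_children,sam_all_pct,mam_all_pct,excluded_sam_pct,underestimated_sam_pct,ignored_risk_sam_pct,correctly_detected_sam_pct,excluded_mam_pct,mam_in_program_pct,rutf_allocation_increase
East Asia and Pacific,15,8671,3.0,13.1,27.1,25.6,17.9,29.4,58.2,71.4,2.55
Latin America and Caribbean,24,13156,1.2,4.8,28.4,14.2,21.6,35.8,49.8,73.1,2.67
South Asia,132,82644,4.2,13.5,26.8,19.1,16.9,37.2,48.2,69.3,2.39
East and South Africa,138,103924,3.8,15.0,35.1,24.4,16.2,24.3,62.6,69.7,2.14
West and Central Africa,87,57445,3.5,11.4,21.4,23.5,24.9,30.2,49.9,67.4,2.41
DRC,154,134298,3.6,10.6,19.2,14.1,13.4,53.3,35.6,70.2,2.72
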