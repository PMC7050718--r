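region,excluded_sam_under24m_pct,underestimated_sam_under24m_pct,ignored_risk_sam_under24m_pct,correctly_detected_sam_under24m_pct,excluded_mam_under24m_pct,included_mam_under24m_pct,excluded_sam_female_pct,underestimated_sam_female_pct,ignored_risk_sam_female_pct,correctly_detected_sam_female_pct,excluded_mam_female_pct,included_mam_female_pct
East Asia and Pacific,19.7,64.2,74.5,76.6,31.1,75.3,32.4,40.3,51.1,66.2,42.2,64.4
Latin America and Caribbean,39.1,73.9,77.1,70.7,40.1,68.7,50.0,17.4,57.1,58.6,35.7,58.2
South Asia,35.3,64.5,87.8,82.7,33.4,73.2,39.1,39.3,47.3,66.2,39.6,59.0
East and South Africa,21.5,63.4,82.1,82.9,25.0,74.0,38.8,34.5,45.6,64.8,41.7,58.5
West and Central Africa,38.1,66.4,77.2,77.4,35.9,69.7,34.6,32.3,46.7,65.4,39.0,60.7
DRC,27.5,44.7,65.9,72.3,27.1,65.4,37.9,35.9,42.3,57.0,39.9,55.4
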