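region,excluded_sam_under24m_pct,underestimated_sam_under24m_pct,ignored_risk_sam_under24m_pct,correctly_detected_sam_under24m_pct,excluded_mam_under24m_pct,included_mam_under24m_pct,excluded_sam_female_pct,underestimated_sam_female_pct,ignored_risk_sam_female_pct,correctly_detected_sam_female_pct,excluded_mam_female_pct,included_mam_female_pct
Overall,28.4,59.8,78.0,77.1,29.1,70.0,38.2,35.6,45.6,61.5,40.4,57.9
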