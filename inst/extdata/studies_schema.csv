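column,type,description
study_id,character,Unique study label
design,character,comparative or descriptive
measure,character,"HR, RR, or OR (comparative studies only)"
orig_n_exp,integer,Original study: exposure-arm subjects
orig_events_exp,integer,Original study: exposure-arm outcome events (optional)
orig_risk_exp,double,Original study: exposure-arm outcome risk in percent (optional)
orig_rate_exp,double,Original study: exposure-arm outcome rate per 100 person-years (optional)
orig_py_exp,double,Original study: exposure-arm person-years (optional)
orig_n_ref,integer,Original study: reference-arm subjects (comparative only; reference arm listed last)
orig_events_ref,integer,Original study: reference-arm outcome events (optional)
orig_risk_ref,double,Original study: reference-arm outcome risk in percent (optional)
orig_rate_ref,double,Original study: reference-arm outcome rate per 100 person-years (optional)
orig_py_ref,double,Original study: reference-arm person-years (optional)
orig_est,double,Original study: effect estimate on ratio scale (comparative only)
orig_ci_low,double,Original study: 95% CI lower bound (optional)
orig_ci_high,double,Original study: 95% CI upper bound (optional)
orig_p,double,Original study: two-sided p-value (optional; absence is meaningful)
repro_n_exp,integer,Reproduction: exposure-arm subjects
repro_events_exp,integer,Reproduction: exposure-arm outcome events (optional)
repro_risk_exp,double,Reproduction: exposure-arm outcome risk in percent (optional)
repro_rate_exp,double,Reproduction: exposure-arm outcome rate per 100 person-years (optional)
repro_py_exp,double,Reproduction: exposure-arm person-years (optional)
repro_n_ref,integer,Reproduction: reference-arm subjects (comparative only)
repro_events_ref,integer,Reproduction: reference-arm outcome events (optional)
repro_risk_ref,double,Reproduction: reference-arm outcome risk in percent (optional)
repro_rate_ref,double,Reproduction: reference-arm outcome rate per 100 person-years (optional)
repro_py_ref,double,Reproduction: reference-arm person-years (optional)
repro_est,double,Reproduction: effect estimate on ratio scale (comparative only)
repro_ci_low,double,Reproduction: 95% CI lower bound (optional)
repro_ci_high,double,Reproduction: 95% CI upper bound (optional)
repro_p,double,Reproduction: two-sided p-value (optional)
funding_source,character,Subgroup attribute: funding source of the original study
data_source,character,Subgroup attribute: healthcare database analysed
publication_year,double,Subgroup attribute: year the original study was published
journal_impact_band,character,Subgroup attribute: journal impact band (high/medium/low)
author_responsive,logical,Subgroup attribute: corresponding author responded to queries
same_group,logical,Subgroup attribute: original authors in the reproduction team's group
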