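item_id,label,category,applies_to
item_01,cohort entry (index) date definition detail 1 (synthetic item wording),index_date,both
item_02,cohort entry (index) date definition detail 2 (synthetic item wording),index_date,both
item_03,cohort entry (index) date definition detail 3 (synthetic item wording),index_date,both
item_04,cohort entry (index) date definition detail 4 (synthetic item wording),index_date,both
item_05,cohort entry (index) date definition detail 5 (synthetic item wording),index_date,both
item_06,cohort entry (index) date definition detail 6 (synthetic item wording),index_date,both
item_07,cohort entry (index) date definition detail 7 (synthetic item wording),index_date,both
item_08,cohort entry (index) date definition detail 8 (synthetic item wording),index_date,both
item_09,cohort entry (index) date definition detail 9 (synthetic item wording),index_date,both
item_10,inclusion-exclusion criterion detail 1 (synthetic item wording),inclusion_exclusion,both
item_11,inclusion-exclusion criterion detail 2 (synthetic item wording),inclusion_exclusion,both
item_12,inclusion-exclusion criterion detail 3 (synthetic item wording),inclusion_exclusion,both
item_13,inclusion-exclusion criterion detail 4 (synthetic item wording),inclusion_exclusion,both
item_14,inclusion-exclusion criterion detail 5 (synthetic item wording),inclusion_exclusion,both
item_15,inclusion-exclusion criterion detail 6 (synthetic item wording),inclusion_exclusion,both
item_16,inclusion-exclusion criterion detail 7 (synthetic item wording),inclusion_exclusion,both
item_17,inclusion-exclusion criterion detail 8 (synthetic item wording),inclusion_exclusion,both
item_18,inclusion-exclusion criterion detail 9 (synthetic item wording),inclusion_exclusion,both
item_19,exposure definition detail 1 (synthetic item wording),exposure,comparative
item_20,exposure definition detail 2 (synthetic item wording),exposure,comparative
item_21,exposure definition detail 3 (synthetic item wording),exposure,comparative
item_22,exposure definition detail 4 (synthetic item wording),exposure,comparative
item_23,exposure definition detail 5 (synthetic item wording),exposure,comparative
item_24,exposure definition detail 6 (synthetic item wording),exposure,comparative
item_25,exposure definition detail 7 (synthetic item wording),exposure,comparative
item_26,exposure definition detail 8 (synthetic item wording),exposure,comparative
item_27,exposure definition detail 9 (synthetic item wording),exposure,comparative
item_28,outcome definition detail 1 (synthetic item wording),outcome,both
item_29,outcome definition detail 2 (synthetic item wording),outcome,both
item_30,outcome definition detail 3 (synthetic item wording),outcome,both
item_31,outcome definition detail 4 (synthetic item wording),outcome,both
item_32,outcome definition detail 5 (synthetic item wording),outcome,both
item_33,outcome definition detail 6 (synthetic item wording),outcome,both
item_34,outcome definition detail 7 (synthetic item wording),outcome,both
item_35,outcome definition detail 8 (synthetic item wording),outcome,both
item_36,outcome definition detail 9 (synthetic item wording),outcome,both
item_37,follow-up window detail 1 (synthetic item wording),follow_up,both
item_38,follow-up window detail 2 (synthetic item wording),follow_up,both
item_39,follow-up window detail 3 (synthetic item wording),follow_up,both
item_40,follow-up window detail 4 (synthetic item wording),follow_up,both
item_41,follow-up window detail 5 (synthetic item wording),follow_up,both
item_42,follow-up window detail 6 (synthetic item wording),follow_up,both
item_43,follow-up window detail 7 (synthetic item wording),follow_up,both
item_44,follow-up window detail 8 (synthetic item wording),follow_up,both
item_45,follow-up window detail 9 (synthetic item wording),follow_up,both
item_46,covariate measurement detail 1 (synthetic item wording),covariates,both
item_47,covariate measurement detail 2 (synthetic item wording),covariates,both
item_48,covariate measurement detail 3 (synthetic item wording),covariates,both
item_49,covariate measurement detail 4 (synthetic item wording),covariates,both
item_50,covariate measurement detail 5 (synthetic item wording),covariates,both
item_51,covariate measurement detail 6 (synthetic item wording),covariates,both
item_52,covariate measurement detail 7 (synthetic item wording),covariates,both
item_53,covariate measurement detail 8 (synthetic item wording),covariates,both
item_54,covariate measurement detail 9 (synthetic item wording),covariates,both
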