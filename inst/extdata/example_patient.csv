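patient_id,age,sex,race_black,scr_pre,egfr_pre_global,egfr_nbgfr_observed,srf_nrs,vol_contra,vol_ipsi_plus_tumor,vol_tumor,lwh_contra_length,lwh_contra_ap1,lwh_contra_ap2,lwh_contra_ml1,lwh_contra_ml2,lwh_ipsi_length,lwh_ipsi_ap1,lwh_ipsi_ap2,lwh_ipsi_ml1,lwh_ipsi_ml2
EX01,60,male,FALSE,,70,47,,210,229,39,11.0,4.2,4.2,4.1,4.1,11.3,4.8,4.8,3.6,3.6
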