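trial,outcome_scale,intervention_type,duration_weeks,n_control,n_intervention,n_fup_control,n_fup_intervention,compliers_n,missing_adherence_n,baseline_mean_control,baseline_sd_control,baseline_mean_intervention,baseline_sd_intervention,fup_mean_control,fup_sd_control,fup_mean_intervention,fup_sd_intervention,resp_no_control,resp_yes_control,resp_no_intervention,resp_yes_intervention,responder_rule
COBALT,BDI,CBT,26,235,234,213,206,144,0,31.83,11,31.76,10,24.51,13,18.94,14,167,46,111,95,half_reduction
GENPOD,BDI,antidepressant,6,303,298,272,274,239,0,33.41,10,33.94,9,19.58,11,18.87,11,211,61,214,60,half_reduction
HEALTHLINES,PHQ9,telehealth,17,302,307,261,255,218,6,16.68,5,17.06,5,11.89,6,11.56,6,175,86,160,95,below10_and_minus5
IPCRESS,BDI,CBT,17,147,148,94,112,90,0,33.46,9,32.87,8,22.09,13,14.51,11,73,21,70,42,below10
MIR,BDI,antidepressant,12,239,241,217,214,151,32,30.64,10,31.48,10,19.69,12,17.97,12,139,78,119,95,half_reduction
PANDA,PHQ9,antidepressant,6,329,323,285,266,241,66,12.20,6,11.76,6,8.75,6,7.98,6,121,164,97,169,half_reduction
TREAD,BDI,physical_activity,17,179,182,146,142,103,0,32.07,10,32.05,9,16.87,13,16.12,11,94,52,102,40,half_reduction
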