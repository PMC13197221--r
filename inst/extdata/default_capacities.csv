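cadre,nhs_hours_per_week,leave_weeks
dentist,26.7,4.4
dh_dth,11.8,4.4
eddn,26.7,4.4
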