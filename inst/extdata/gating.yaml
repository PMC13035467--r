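# A-priori gating order of the non-inferiority/superiority tests for each of
# the ten combination workflows. Metric labels: CDR (cancer detection rate),
# RR (recall rate), SEN (sensitivity), SPEC (specificity), PPV (positive
# predictive value). Tests run in order; the first non-inferiority failure
# makes every later test exploratory.
trineg_OP3_plus_addread_OP2: [CDR, RR, SEN, SPEC, PPV]
trineg_OP3_plus_addread_OP1: [CDR, RR, SEN, SPEC, PPV]
trineg_OP4_plus_addread_OP2: [RR, SPEC, SEN, CDR, PPV]
trineg_OP4_plus_addread_OP1: [RR, SPEC, SEN, CDR, PPV]
trineg_OP2_plus_addread_OP2: [RR, SPEC, PPV, SEN, CDR]
trineg_OP2_plus_addread_OP1: [RR, SPEC, PPV, SEN, CDR]
triage_OP2_plus_addread_OP2: [RR, SPEC, SEN, CDR, PPV]
triage_OP2_plus_addread_OP1: [RR, SPEC, SEN, CDR, PPV]
triage_OP1_plus_addread_OP2: [RR, SPEC, SEN, CDR, PPV]
triage_OP1_plus_addread_OP1: [RR, SPEC, SEN, CDR, PPV]
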