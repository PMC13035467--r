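# The 17 evaluated AI workflow configurations.
# additional_read: AI flags routine non-recalls for extra human arbitration.
# triage: AI replaces reader 2 when it agrees with reader 1.
# triage_negatives: AI replaces reader 2 only on agreed no-recalls.
# Combinations apply the triage component first, then the additional read.
- {mode: additional_read, op_additional: OP2}
- {mode: additional_read, op_additional: OP1}
- {mode: triage, op_triage: OP1}
- {mode: triage, op_triage: OP2}
- {mode: triage_negatives, op_triage: OP2}
- {mode: triage_negatives, op_triage: OP3}
- {mode: triage_negatives, op_triage: OP4}
- {mode: trineg_plus_additional, op_triage: OP3, op_additional: OP2}
- {mode: trineg_plus_additional, op_triage: OP3, op_additional: OP1}
- {mode: trineg_plus_additional, op_triage: OP4, op_additional: OP2}
- {mode: trineg_plus_additional, op_triage: OP4, op_additional: OP1}
- {mode: trineg_plus_additional, op_triage: OP2, op_additional: OP2}
- {mode: trineg_plus_additional, op_triage: OP2, op_additional: OP1}
- {mode: triage_plus_additional, op_triage: OP2, op_additional: OP2}
- {mode: triage_plus_additional, op_triage: OP2, op_additional: OP1}
- {mode: triage_plus_additional, op_triage: OP1, op_additional: OP2}
- {mode: triage_plus_additional, op_triage: OP1, op_additional: OP1}
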