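patient_id,reference_label
PD-1,PD
PD-2,PD
PD-3,PD
PD-4,PD
NP-1,non-PD
NP-2,non-PD
NP-3,non-PD
NP-4,non-PD
NP-5,non-PD
NP-6,non-PD
NP-7,non-PD
NP-8,non-PD
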