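patient
examination
symptom
disease
past_history
operation_recording
treatment_options
physical_examination
food
drug
department
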