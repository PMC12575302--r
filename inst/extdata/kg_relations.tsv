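relation	domain	range
recommand_drug	disease	drug
has_symptom	disease	symptom
recommand_eat	disease	food
need_check	disease	examination
no_eat	disease	food
do_eat	disease	food
drugs_of	disease	drug
rels_diseases	disease	disease
common_drug	disease	drug
accompany_with	disease	disease
belongs_to	*	*
rels_body	patient	physical_examination
rels_operation	patient	operation_recording
rels_disease	patient	disease
rels_symptom	patient	symptom
rels_check	patient	examination
rels_treatment	patient	treatment_options
rels_condition	patient	past_history
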