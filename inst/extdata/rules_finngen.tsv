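pattern	table	column	transform
endpoint_name	item	source_id	identity
trait_name	cohort	trait_name	identity
n_cases	cohort	initial_cases	integer
n_controls	cohort	initial_controls	integer
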