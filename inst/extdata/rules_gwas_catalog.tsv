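pattern	table	column	transform
study_accession	item	source_id	identity
pubmed_id	case_study	pubmed_id	identity
disease_trait	cohort	trait_name	identity
initial_sample_size	cohort	initial_individuals	integer
replication_sample_size	cohort	replication_individuals	integer
stage_([0-9]+)	ancestry	stage	identity
broad_ancestral_category_([0-9]+)	ancestry	broad_ancestral_category	identity
country_of_origin_([0-9]+)	ancestry	country_of_origin	identity
country_of_recruitment_([0-9]+)	ancestry	country_of_recruitment	identity
number_of_individuals_([0-9]+)	ancestry	number_of_individuals	integer
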