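# Default mapping for CELLxGENE-shaped observation metadata.
# The 10 common variables have fixed targets in the model; every common
# variable's companion `<var>_ontology_term_id` (or `<var>_ontology_id`)
# column fills the paired ontology-ID column of its target attribute.
# All other observation columns are routed to extended attributes of the
# per-observation Result record.
id_prefix: "CXG:"
metadata:
  sample_id: sample_id
  observation_join_id: observation_join_id
common_variables:
  organism:            {class: Subject,    attribute: organism}
  species:             {class: Subject,    attribute: species}
  developmental_stage: {class: Subject,    attribute: developmental_stage}
  sex:                 {class: Subject,    attribute: sex}
  disease:             {class: Occurrence, attribute: disease}
  tissue:              {class: Sample,     attribute: tissue}
  tissue_type:         {class: Sample,     attribute: tissue_type}
  suspension:          {class: Sample,     attribute: suspension}
  assay:               {class: Assay,      attribute: assay_type}
  cell_type:           {class: Result,     attribute: cell_type}
dataset_name: "CELLxGENE import"
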