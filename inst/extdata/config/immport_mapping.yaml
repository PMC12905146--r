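# Default mapping for ImmPort-shaped per-table CSV dumps.
# The three intervention-type tables are concatenated into Intervention,
# the three sample tables into Sample (with the controlled `type` column),
# and each assay-specific table becomes Assay rows (one per distinct assay
# accession) plus Result rows (one per source row).
# The published model does not enumerate the full source-column crosswalk,
# so the column maps below are provisional defaults.
provisional: true
id_prefix: "IMMPORT:"
tables:
  study:
    class: Study
    columns: {study_accession: study_id, name: name, start_date: start_date}
  experiment:
    class: Experiment
    columns: {experiment_accession: experiment_id, study_accession: study_id,
              name: name}
  subject:
    class: Subject
    columns: {subject_accession: subject_id,
              experiment_accession: experiment_id,
              age_reported: age, gender: sex, species: species}
intervention_tables: [intervention, immune_exposure, treatment]
intervention_columns:
  intervention_accession: intervention_id
  subject_accession: subject_id
  name_reported: material
  material_vo_id: material_ontology_id
  type_reported: intervention_type
  dose_reported: dose
  route_reported: route
  start_day: intervention_time
sample_tables: {biosample: biosample, control_sample: control,
                expsample: expsample}
sample_columns:
  sample_accession: sample_id
  subject_accession: subject_id
  collection_method: collection
  study_time_collected: collection_time
  biosample_source: biosample_source
  subtype: expsample_type
  biosample_accession: biosample_reference_name
  expsample_accession: expsample_reference_name
  batch: batch
assay_table_prefix: "assay_"
assay_columns:
  result_accession: result_id
  assay_accession: assay_id
  expsample_accession: sample_id
  experiment_accession: experiment_id
  datatype: datatype
  filetype: filetype
  reference_name: reference_name
  platform: platform
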