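# Default mapping for VIGET-shaped input: one study/sample metadata table
# (one row per experimental sample) plus one normalized log2 expression
# matrix keyed by GEO-style sample reference names.
# `columns` maps semantic roles to source column names; the source column
# list is not published, so these defaults are provisional and meant to be
# overridden for a concrete export.
provisional: true
id_prefix: "VIGET:"
columns:
  study: study_accession
  study_name: study_title
  subject: subject_accession
  species: species
  sex: sex
  age: age
  vaccine: vaccine
  vaccine_vo_id: vaccine_vo_id
  day: study_time_collected
  expsample_ref: geo_accession
  biosample_ref: biosample_accession
  expsample_type: expsample_type
  batch: batch
constants:
  expsample_type: PBMC
  collection: blood draw
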