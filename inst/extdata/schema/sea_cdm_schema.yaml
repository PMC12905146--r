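# SEA CDM schema definition.
#
# 13 classes: 10 core (Study, Experiment, Assay, Subject, Sample, Group,
# Intervention, Occurrence, Analysis, Result) and 3 accessory (Material,
# Ontology, Documentation).  `category` follows the Basic Formal Ontology
# split used by the model: process / material_entity / data_item.
#
# Attribute fields:
#   kind           one of text, number, date, identifier, controlled
#   ontology_pair  true => a paired `<name>_ontology_id` column exists
#   required       true => value must be non-empty (primary keys always are)
#   values         enumerated domain for `controlled` attributes
#   provisional    true => attribute completed by this implementation; the
#                  published model enumerates only a representative subset
#                  of attributes per class, so non-representative columns
#                  are flagged here as implementer-defined.
#
# Documentation and Ontology link to any core class through the polymorphic
# (target_class, target_id) pair rather than a typed foreign key.
classes:
  Study:
    kind: core
    category: process
    primary_key: study_id
    attributes:
      - {name: name, kind: text}
      - {name: title, kind: text, provisional: true}
      - {name: description, kind: text, provisional: true}
      - {name: start_date, kind: date, provisional: true}
      - {name: study_type, kind: controlled, ontology_pair: true, provisional: true}
    foreign_keys: []
  Experiment:
    kind: core
    category: process
    primary_key: experiment_id
    attributes:
      - {name: name, kind: text}
      - {name: description, kind: text, provisional: true}
      - {name: experiment_type, kind: controlled, ontology_pair: true, provisional: true}
    foreign_keys:
      - {column: study_id, target_class: Study, target_column: study_id}
  Assay:
    kind: core
    category: process
    primary_key: assay_id
    attributes:
      - {name: assay_type, kind: controlled, ontology_pair: true}
      - {name: organism_inclusion, kind: text, ontology_pair: true}
      - {name: reagents, kind: text, ontology_pair: true}
      - {name: platform, kind: text, ontology_pair: true}
    foreign_keys:
      - {column: experiment_id, target_class: Experiment, target_column: experiment_id}
      - {column: sample_id, target_class: Sample, target_column: sample_id}
  Subject:
    kind: core
    category: material_entity
    primary_key: subject_id
    attributes:
      - {name: age, kind: number}
      - {name: sex, kind: controlled, ontology_pair: true}
      - {name: species, kind: text, ontology_pair: true}
      - {name: race, kind: text, ontology_pair: true}
      - {name: ethnicity, kind: text, ontology_pair: true}
      - {name: strain, kind: text, ontology_pair: true}
      - {name: organism, kind: text, ontology_pair: true, provisional: true}
      - {name: developmental_stage, kind: text, ontology_pair: true, provisional: true}
    foreign_keys:
      - {column: experiment_id, target_class: Experiment, target_column: experiment_id}
      - {column: group_id, target_class: Group, target_column: group_id}
  Sample:
    kind: core
    category: material_entity
    primary_key: sample_id
    attributes:
      - {name: type, kind: controlled, values: [biosample, expsample, control]}
      - {name: collection, kind: text, ontology_pair: true}
      - {name: collection_time, kind: number}
      - {name: biosample_source, kind: text, ontology_pair: true}
      - {name: expsample_type, kind: text, ontology_pair: true}
      - {name: biosample_reference_name, kind: identifier, provisional: true}
      - {name: expsample_reference_name, kind: identifier, provisional: true}
      - {name: batch, kind: text, provisional: true}
      - {name: tissue, kind: text, ontology_pair: true, provisional: true}
      - {name: tissue_type, kind: text, ontology_pair: true, provisional: true}
      - {name: suspension, kind: text, ontology_pair: true, provisional: true}
    foreign_keys:
      - {column: subject_id, target_class: Subject, target_column: subject_id}
  Group:
    kind: core
    category: material_entity
    primary_key: group_id
    attributes:
      - {name: name, kind: text, provisional: true}
      - {name: description, kind: text, provisional: true}
    foreign_keys:
      - {column: experiment_id, target_class: Experiment, target_column: experiment_id}
  Intervention:
    kind: core
    category: process
    primary_key: intervention_id
    attributes:
      - {name: intervention_type, kind: controlled, ontology_pair: true}
      - {name: material, kind: text, ontology_pair: true}
      - {name: intervention_time, kind: number}
      - {name: dose, kind: text}
      - {name: route, kind: text, ontology_pair: true}
    foreign_keys:
      - {column: subject_id, target_class: Subject, target_column: subject_id}
      - {column: material_id, target_class: Material, target_column: material_id}
  Occurrence:
    kind: core
    category: process
    primary_key: occurrence_id
    attributes:
      - {name: occurrence_type, kind: controlled, ontology_pair: true, provisional: true}
      - {name: disease, kind: text, ontology_pair: true, provisional: true}
      - {name: occurrence_time, kind: number, provisional: true}
    foreign_keys:
      - {column: subject_id, target_class: Subject, target_column: subject_id}
  Analysis:
    kind: core
    category: process
    primary_key: analysis_id
    attributes:
      - {name: name, kind: text, provisional: true}
      - {name: description, kind: text, provisional: true}
    foreign_keys:
      - {column: group_id, target_class: Group, target_column: group_id}
      - {column: result_id, target_class: Result, target_column: result_id}
  Result:
    kind: core
    category: data_item
    primary_key: result_id
    attributes:
      - {name: datatype, kind: text, ontology_pair: true}
      - {name: original_assay_type, kind: text}
      - {name: filetype, kind: text}
      - {name: value, kind: text, provisional: true}
      - {name: reference_name, kind: identifier, provisional: true}
      - {name: cell_type, kind: text, ontology_pair: true, provisional: true}
    foreign_keys:
      - {column: assay_id, target_class: Assay, target_column: assay_id}
  Material:
    kind: accessory
    category: material_entity
    primary_key: material_id
    attributes:
      - {name: name, kind: text, ontology_pair: true}
      - {name: type, kind: text, ontology_pair: true, provisional: true}
      - {name: manufacturer, kind: text, provisional: true}
    foreign_keys: []
  Ontology:
    kind: accessory
    category: data_item
    primary_key: ontology_id
    attributes:
      - {name: name, kind: text, provisional: true}
      - {name: version, kind: text, provisional: true}
      - {name: url, kind: text, provisional: true}
      - {name: target_class, kind: identifier, provisional: true}
      - {name: target_id, kind: identifier, provisional: true}
    foreign_keys: []
  Documentation:
    kind: accessory
    category: data_item
    primary_key: documentation_id
    attributes:
      - {name: doc_type, kind: text, ontology_pair: true, provisional: true}
      - {name: path, kind: text, provisional: true}
      - {name: description, kind: text, provisional: true}
      - {name: target_class, kind: identifier, provisional: true}
      - {name: target_id, kind: identifier, provisional: true}
    foreign_keys: []
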