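---
title: "The SEA CDM engine: model, statistic, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SEA CDM engine: model, statistic, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seacdm)
```

## The model

The Study-Experiment-Assay common data model (SEA CDM) is a deliberately
small schema for cross-source integration of biomedical study metadata.
Thirteen classes cover the recurring pattern of interventional studies:

* **process classes** — Study, Experiment, Assay, Intervention, Occurrence,
  Analysis;
* **material-entity classes** — Subject, Sample, Group (and the accessory
  Material);
* **data-item classes** — Result (and the accessory Ontology and
  Documentation).

Ten classes are *core* and linked by foreign keys (an Experiment belongs to
a Study, a Subject to an Experiment, Samples to Subjects, Assays to
Experiments and Samples, Results to Assays, and so on); Material, Ontology,
and Documentation are *accessory*, attachable to any core class — Material
through the Intervention's typed key, Ontology and Documentation through a
polymorphic `(target_class, target_id)` link. Every descriptive attribute
can carry a paired `<attribute>_ontology_id` column, which is what makes
values from different sources interoperable: two sources may spell a
vaccine differently, but both can point at the same ontology identifier.

The published description of the model enumerates only representative
attributes per class. Where this package completes a class beyond that list
(for example `Sample$biosample_reference_name`, visible in the model's own
summary SQL, or the CELLxGENE-motivated `Subject$developmental_stage`),
the attribute is flagged `provisional: true` in the machine-readable schema
(`inst/extdata/schema/sea_cdm_schema.yaml`), so downstream users can tell
the canonical surface from the implementation-defined completion. Group and
Analysis, whose attributes are never enumerated, get minimal definitions
(identifier, name, description, foreign keys).

One representational choice deserves a note: the three source sample tables
found in relational repositories (biosample, control sample, experimental
sample) are merged into a single Sample class with a controlled
`type ∈ {biosample, expsample, control}` column. This is lossless — the
source table of each merged row is preserved as a `source_table` extended
attribute — and it lets the canonical summary query run over one table.

## The stimulated-gene statistic

The analysis payload answers questions of the form *"which genes are
stimulated by vaccine V in species S at day D after vaccination?"*. It has
two stages.

**Pair selection.** For every subject matching the query (intervention
material, optional species and sex), the store is queried for experimental
samples at the baseline day (default 0) and the follow-up day; subjects
lacking either are excluded. When the query material is an ontology term id
and a term graph is supplied, matching expands over the term's descendants,
self included — so `VO_0001236` (trivalent influenza vaccine) selects
Fluarix, Fluvirin, Fluzone, and FluMist interventions at once, by
descendant label or by the intervention's own ontology id. If a subject has
several samples at one day, the lexicographically first sample reference is
used, with a warning; this tie-break is arbitrary but deterministic.

**Filtering.** Let $x_{g,s}(d)$ be the normalized log2 expression of gene
$g$ in subject $s$ at day $d$. A subject pair *passes* for gene $g$ when

$$x_{g,s}(D) - x_{g,s}(0) \ge f \quad\text{and}\quad
  \max\bigl(x_{g,s}(D),\, x_{g,s}(0)\bigr) \ge c,$$

and $g$ is **stimulated** when at least $m$ pairs pass. Defaults are
$f = 1$ log2 unit (a 2-fold change), $c = 0.2$ log2 units (an expression
floor that discards fold changes between two near-zero values), and
$m = 3$ subjects. All three comparisons are *inclusive* — "at least" — so a
delta of exactly 1.0 with a follow-up value of exactly 0.2 passes; the test
suite pins these boundaries. Before filtering, any pair touching a
batch-flagged sample is removed (batch effects are excluded, not adjusted;
there is deliberately no batch-correction step). The subject minimum is
applied to the count of *passing pairs per gene*, i.e. after the two
filters, and "the same gene profile" is read as the same pass/fail outcome
for that gene. Both interpretations are configurable through
`gene_filter_criteria()`.

Raising any of $f$, $c$, $m$ can only shrink the stimulated set
(monotonicity, property-tested), and relaxing them to $f \to 0^+$,
$c = -\infty$, $m = 1$ recovers every gene with any positive delta — a
closed-form sanity check in the suite.

Per-vaccine gene lists can then be grouped by ontology class
(`group_by_vaccine_class()`): each class term's list is the union over
vaccines that are descendants of the term, which is how trivalent
inactivated (TIV) and live attenuated (LAIV) summaries are built. Overlap
counts over the $2^k - 1$ membership regions (`overlap_counts()`) support
Venn-style summaries without any plotting dependency; rendering is out of
scope, as is pathway enrichment — gene lists are exported in CSV/JSON for
external enrichment services.

## The relational store and the knowledge graph

The same bundle can be materialized two ways, and both must answer
identically; this dual-route property is tested.

The **store** is an embedded SQLite database created from the registry's
DDL (`CREATE TABLE IF NOT EXISTS`, so re-initialization is a safe no-op);
loading is append-only and atomic — a bundle is validated (including full
referential integrity) before a single row is written, and duplicate
primary keys abort the load naming the class and key. A MySQL-dialect DDL
is emitted for server deployments, but no server is required anywhere in
the package. The canonical summary query counts distinct biosample
reference names, study ids, and expsample reference names over the
Sample ⋈ Subject ⋈ Intervention ⋈ Experiment join for an explicit
material list; matching there is an exact string `IN`-list by design, with
ontology expansion reserved for pair selection.

The **knowledge graph** gives every record a node labelled by its class and
every ontology term a node, with edges for each non-null foreign key, each
`subClassOf` assertion, and an `instance_of_term` edge wherever a record's
`_ontology_id` value matches a loaded term. `materials_under()` implements
the zero-or-more-hop traversal (Cypher `subClassOf*`): instances of the
query term itself count, matching graph-database semantics, whereas
`descendants()` with `include_self = FALSE` matches the one-or-more-hop
SPARQL reading — both are exposed because the two query languages disagree
on the zero-hop case. Exports are plain text: bulk-import CSVs
(`:ID`/`:LABEL`/`:START_ID`/`:END_ID`/`:TYPE`) and a Cypher script with one
`MERGE` per node and edge. Ontology terms are stored as CURIEs with a URI
property.

The ontology loader itself accepts a three-column term table or an RDF/XML
subset restricted to named classes and `rdfs:subClassOf` — full OWL
reasoning, equivalence axioms, and live endpoint queries are out of scope.
Cycles over `subClassOf` are an error (with the cycle listed), undeclared
parents are kept with a warning, and duplicate labels resolve to the
lowest id, again with a warning. Transitive closure is computed by plain
frontier expansion; the test suite checks it against an independent
graph-library closure on random DAGs of up to 500 nodes. Whether a
hierarchy count should include only named subclasses is ambiguous in
SPARQL practice; named subclasses only is implemented.

## The synthetic-data generator

`simulate_study()` emulates the canonical vaccine-study pattern: each study
uses one vaccine (name + ontology id, drawn round-robin from Fluarix /
Fluvirin / Fluzone / FluMist by default); each subject is vaccinated at
day 0 and contributes, at each visit day (default 0/7/14/28), a blood
biosample and a derived PBMC expsample whose GEO-style reference name keys
the expression matrix.

Expression is baseline $\mathcal N(5, \sigma)$ per gene and sample on the
log2 scale, with a planted set of genes gaining a fixed increment $\Delta$
at post-baseline days in responder subjects. Defaults — 3 studies,
10 subjects per study, 200 genes with 20 planted, $\Delta = 2$,
$\sigma = 0.1$, 5% of expsamples batch-flagged, all subjects responders —
were chosen once as a realistic desk-scale rendering of multi-study vaccine
cohorts: 8–12 subjects per arm is a typical systems-vaccinology cohort
size, a 2 log2-unit response with $\sigma = 0.1$ reflects that curated,
normalized expression values vary far less than raw counts, and a small
batch fraction exercises the exclusion path without dominating. A
`responder_fraction` below 1 supports boundary tests of the subject
minimum. The noise model is independent Gaussian on the log2 scale — the
simplest model consistent with normalized log2 inputs. It is a stand-in,
not a claim about repository data: real transcriptomes have correlated
genes, heavier tails, and structured batch effects, so passing tests here
demonstrate correctness of the *filtering logic and plumbing*, not
recovery guarantees on real data. Single-cell count matrices are likewise
not simulated; the CELLxGENE emulation produces observation *metadata*
only.

All generation is driven by one integer seed; identical configurations
yield byte-identical bundles, matrices, and truth records. The same
generator also writes the three source layouts (the two-file
metadata+matrix form; the relational dump with separate intervention /
immune-exposure / treatment and biosample / control / expsample tables plus
per-assay files; and the per-observation table with the 10 common variables,
their ontology-id companions, two metadata columns, and optional author
variables), so every connector is tested round-trip with row conservation.

## ETL conventions

Connectors are configuration-driven (`inst/extdata/config/*.yaml`) because
none of the source column inventories is fully published; the shipped maps
are marked provisional and meant to be overridden per export. Three
conventions apply uniformly: identifiers are prefixed per source (`VIGET:`,
`IMMPORT:`, `CXG:`) so bundles merge into one store without collisions;
unmapped source columns are never dropped or fatal — they land in the
long-format extended-attribute table keyed by class and record; and merges
concatenate, never deduplicate, so every source row maps to exactly one row
of its destination class. A missing common variable in observation input
warns and yields nulls rather than failing. H5ad files are read via their
HDF5 observation group when rhdf5 is available; a pre-flattened CSV of
observations is always accepted, so no HDF5 fixture is ever required.

## Numerical and formatting choices

* CSV dialect: UTF-8, comma, RFC 4180 quoting, header row; empty string
  encodes null, booleans as `"true"`/`"false"`. Ragged rows are an error
  naming file and line.
* Ontology-ID columns sit immediately after their attribute in templates
  (adjacency is unspecified upstream; adjacent is friendlier to hand
  editing and is documented here).
* Bundle columns are typed by the schema (`number` → numeric, the rest
  character); the store maps these to REAL/TEXT, which is what makes
  write→read and load→dump exact identities rather than
  approximately-equal round trips.
* An ontology id with an empty base value is a validation violation
  (`orphan_ontology_id`); a value without an id is fine.
* The filter's thresholds are compared with `>=` on doubles; no tolerance
  is added, since inputs are data, not iterates.

## Problem sizes in the shipped checks

The test suite and acceptance script run entirely on generated data:
200 random 100-gene × 12-pair matrices against the exhaustive filter
oracle; 50 replicate studies (10 subjects, $\sigma = 0.1$, $\Delta = 2$)
for recovery, which is effectively 100% since the per-pair delta noise is
$\sigma\sqrt 2 \approx 0.14$ against a margin of 1; 20 synthetic stores for
the SQL-versus-loops agreement; 100 bundle/ontology pairings for the
graph-versus-relational agreement; and random DAGs up to 500 nodes for the
closure oracle. These sizes were chosen as the smallest at which the checks
are still convincing; all scale linearly if enlarged.

## Known limitations

* No schema migration, no OMOP/ISA cross-walks, no server administration.
* No OWL reasoning beyond `subClassOf` closure; no Turtle input.
* Batch-flagged samples are removed, never modeled or corrected.
* The ImmPort and CELLxGENE column crosswalks are provisional defaults, not
  authoritative mappings of those repositories' full schemas.
* Reference counts reported for the real repositories (study totals,
  descendant counts in full ontology releases) are version-dependent and
  are documented rather than asserted by tests.
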