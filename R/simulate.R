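#' Synthetic vaccine-study generator
#'
#' Emulates the canonical vaccine-study pattern: subjects receive an
#' intervention (a vaccine, carried as a Material with its ontology id) at
#' day 0, blood biosamples are drawn at each visit day and processed into
#' PBMC experimental samples, and a transcription-profiling assay on each
#' expsample yields normalized log2 expression keyed by GEO-style sample
#' reference names.  A configurable subset of genes is "planted": their
#' expression gains a fixed log2 increment at post-baseline days in
#' responder subjects, so downstream filters can be scored against known
#' truth.  All randomness is governed by a single seed.
#'
#' @name synthetic_data
NULL

default_vaccines <- function() {
  data.frame(
    name = c("Fluarix", "Fluvirin", "Fluzone", "FluMist"),
    vo_id = c("VO_9100001", "VO_9100002", "VO_0000047", "VO_9100004"),
    class = c("TIV", "TIV", "TIV", "LAIV"),
    route = c("intramuscular", "intramuscular", "intramuscular",
              "intranasal"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param n_studies Number of studies; vaccines are assigned to studies
#'   round-robin.
#' @param subjects_per_study Subjects enrolled per study.
#' @param sex_ratio Proportion of female subjects (assigned
#'   deterministically: the first `round(n * sex_ratio)` per study).
#' @param vaccines Data frame with columns name, vo_id, class, route.
#' @param days Visit days; day 0 is the pre-vaccination baseline.
#' @param n_genes Genes in the expression matrix.
#' @param planted_genes Number of truly stimulated genes.
#' @param planted_delta Log2 increment added for planted genes at
#'   post-baseline days in responders.
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param batch_fraction Proportion of expsamples flagged as batch-affected.
#' @param responder_fraction Proportion of subjects that respond.
#' @param extra_vars Author-specific variables in the CELLxGENE emulation.
#' @param cells_per_sample Observation rows per sample in the CELLxGENE
#'   emulation.
#' @param seed Integer seed; identical configs produce identical outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_studies = 3, subjects_per_study = 10,
                       sex_ratio = 0.5, vaccines = default_vaccines(),
                       days = c(0, 7, 14, 28), n_genes = 200,
                       planted_genes = 20, planted_delta = 2,
                       noise_sd = 0.1, batch_fraction = 0.05,
                       responder_fraction = 1, extra_vars = 0,
                       cells_per_sample = 1, seed = 42) {
  cfg <- list(n_studies = n_studies, subjects_per_study = subjects_per_study,
              sex_ratio = sex_ratio, vaccines = vaccines, days = sort(days),
              n_genes = n_genes, planted_genes = planted_genes,
              planted_delta = planted_delta, noise_sd = noise_sd,
              batch_fraction = batch_fraction,
              responder_fraction = responder_fraction,
              extra_vars = extra_vars, cells_per_sample = cells_per_sample,
              seed = seed)
  if (planted_genes > n_genes) stop("planted_genes must be <= n_genes")
  if (batch_fraction < 0 || batch_fraction > 1)
    stop("batch_fraction must be in [0, 1]")
  if (planted_delta < 0) stop("planted_delta must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_studies < 1 || subjects_per_study < 0)
    stop("n_studies must be >= 1 and subjects_per_study >= 0")
  if (!0 %in% cfg$days) stop("days must include the baseline day 0")
  structure(cfg, class = "sim_config")
}

#' Simulate a complete multi-study bundle with expression data
#'
#' @param config A [sim_config()].
#' @return A list of class `sea_simulation`: `bundle` (a `sea_bundle` that
#'   passes validation), `matrix` (an `expression_matrix` over the
#'   expsample reference names), and `truth` (planted gene set, responder
#'   subjects, batch-flagged sample references).
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "sim_config")) stop("invalid config")
  with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  nv <- nrow(cfg$vaccines)
  study <- exp <- grp <- subj <- intv <- samp <- assay <- res <- list()
  mat_tb <- data.frame(material_id = id_seq("MAT", seq_len(nv)),
                       name = cfg$vaccines$name,
                       name_ontology_id = cfg$vaccines$vo_id,
                       type = "vaccine", type_ontology_id = "VO_0000001",
                       manufacturer = NA_character_,
                       stringsAsFactors = FALSE)
  subj_ctr <- samp_ctr <- asy_ctr <- 0L
  subjects_all <- character()
  exps_meta <- list()   # per expsample: ref, subject, day

  for (s in seq_len(cfg$n_studies)) {
    vx <- cfg$vaccines[(s - 1) %% nv + 1, ]
    sid <- id_seq("STUDY", s, 2)
    eid <- id_seq("EXP", s, 2)
    gid <- id_seq("GRP", s, 2)
    study[[s]] <- data.frame(
      study_id = sid, name = sprintf("Synthetic %s immunization study", vx$name),
      title = NA, description = NA, start_date = "2020-01-01",
      study_type = "interventional", study_type_ontology_id = NA,
      stringsAsFactors = FALSE)
    exp[[s]] <- data.frame(
      experiment_id = eid, study_id = sid,
      name = "immune response profiling", description = NA,
      experiment_type = NA, experiment_type_ontology_id = NA,
      stringsAsFactors = FALSE)
    grp[[s]] <- data.frame(group_id = gid, experiment_id = eid,
                           name = "vaccinated", description = NA,
                           stringsAsFactors = FALSE)
    n_f <- round(cfg$subjects_per_study * cfg$sex_ratio)
    for (k in seq_len(cfg$subjects_per_study)) {
      subj_ctr <- subj_ctr + 1L
      su <- id_seq("SUBJ", subj_ctr)
      subjects_all <- c(subjects_all, su)
      sex <- if (k <= n_f) "female" else "male"
      subj[[subj_ctr]] <- data.frame(
        subject_id = su, experiment_id = eid, group_id = gid,
        age = sample(18:65, 1), sex = sex,
        sex_ontology_id = if (sex == "female") "PATO_0000383" else "PATO_0000384",
        species = "Homo sapiens", species_ontology_id = "NCBITaxon_9606",
        race = NA, ethnicity = NA, strain = NA, organism = "Homo sapiens",
        organism_ontology_id = "NCBITaxon_9606", developmental_stage = "adult",
        stringsAsFactors = FALSE)
      intv[[subj_ctr]] <- data.frame(
        intervention_id = id_seq("INTV", subj_ctr), subject_id = su,
        material_id = mat_tb$material_id[match(vx$name, mat_tb$name)],
        intervention_type = "vaccination", material = vx$name,
        material_ontology_id = vx$vo_id, intervention_time = 0,
        dose = "1 dose", route = vx$route,
        stringsAsFactors = FALSE)
      for (d in cfg$days) {
        samp_ctr <- samp_ctr + 1L
        bs_id <- id_seq("BS", samp_ctr); bs_ref <- id_seq("BSR", samp_ctr)
        samp[[length(samp) + 1L]] <- data.frame(
          sample_id = bs_id, subject_id = su, type = "biosample",
          collection = "blood draw", collection_time = d,
          biosample_source = "blood", expsample_type = NA,
          biosample_reference_name = bs_ref,
          expsample_reference_name = NA, batch = NA,
          stringsAsFactors = FALSE)
        es_id <- id_seq("ES", samp_ctr)
        es_ref <- sprintf("GSM9%06d", samp_ctr)
        samp[[length(samp) + 1L]] <- data.frame(
          sample_id = es_id, subject_id = su, type = "expsample",
          collection = "blood draw", collection_time = d,
          biosample_source = "blood", expsample_type = "PBMC",
          biosample_reference_name = bs_ref,
          expsample_reference_name = es_ref, batch = NA,
          stringsAsFactors = FALSE)
        asy_ctr <- asy_ctr + 1L
        aid <- id_seq("ASY", asy_ctr)
        assay[[asy_ctr]] <- data.frame(
          assay_id = aid, experiment_id = eid, sample_id = es_id,
          assay_type = "transcription profiling assay",
          assay_type_ontology_id = "OBI_0000424",
          organism_inclusion = "Homo sapiens", reagents = NA,
          platform = "expression microarray",
          stringsAsFactors = FALSE)
        res[[asy_ctr]] <- data.frame(
          result_id = id_seq("RES", asy_ctr), assay_id = aid,
          datatype = "normalized log2 expression",
          original_assay_type = "transcription profiling",
          filetype = "csv", value = NA, reference_name = es_ref,
          stringsAsFactors = FALSE)
        exps_meta[[asy_ctr]] <- data.frame(
          ref = es_ref, subject = su, day = d, study = sid,
          vaccine = vx$name, vo_id = vx$vo_id, sex = sex,
          biosample_ref = bs_ref, sample_id = es_id,
          stringsAsFactors = FALSE)
      }
    }
  }
  samp_tb <- do.call(rbind, samp)
  exps_meta <- do.call(rbind, exps_meta)
  if (is.null(exps_meta))
    exps_meta <- data.frame(ref = character(), subject = character(),
                            day = numeric(), study = character(),
                            vaccine = character(), vo_id = character(),
                            sex = character(), biosample_ref = character(),
                            sample_id = character(), stringsAsFactors = FALSE)

  # batch flags on expsamples (exact count, seeded choice)
  n_exp <- nrow(exps_meta)
  n_batch <- round(cfg$batch_fraction * n_exp)
  batch_refs <- if (n_batch > 0) sample(exps_meta$ref, n_batch) else character()
  if (!is.null(samp_tb))
    samp_tb$batch[samp_tb$expsample_reference_name %in% batch_refs] <- "true"

  # expression: baseline N(5, sd); planted genes +delta post-baseline in
  # responders
  genes <- id_seq("G", seq_len(cfg$n_genes))
  planted <- sort(sample(genes, cfg$planted_genes))
  responders <- sort(sample(subjects_all,
                            round(cfg$responder_fraction *
                                  length(subjects_all))))
  vals <- matrix(stats::rnorm(cfg$n_genes * n_exp, mean = 5,
                              sd = cfg$noise_sd),
                 nrow = cfg$n_genes, dimnames = list(genes, exps_meta$ref))
  bump <- (exps_meta$day > 0) & (exps_meta$subject %in% responders)
  if (any(bump) && length(planted) > 0)
    vals[planted, bump] <- vals[planted, bump] + cfg$planted_delta
  flags <- stats::setNames(exps_meta$ref %in% batch_refs, exps_meta$ref)
  emat <- expression_matrix(vals, batch_flag = flags)

  first_res <- if (length(res)) res[[1]]$result_id else NA
  ana <- data.frame(analysis_id = "ANA0001",
                    group_id = grp[[1]]$group_id,
                    result_id = first_res,
                    name = "stimulated-gene screen", description = NA,
                    stringsAsFactors = FALSE)
  doc <- data.frame(documentation_id = "DOC0001", doc_type = "data file",
                    doc_type_ontology_id = NA,
                    path = "synthetic://expression_matrix.csv",
                    description = "normalized log2 gene expression",
                    target_class = "Study", target_id = study[[1]]$study_id,
                    stringsAsFactors = FALSE)
  ont <- data.frame(ontology_id = "ONT0001", name = "Vaccine Ontology",
                    version = "synthetic-mini", url = NA,
                    target_class = "Material",
                    target_id = mat_tb$material_id[1],
                    stringsAsFactors = FALSE)

  tables <- list(Study = do.call(rbind, study),
                 Experiment = do.call(rbind, exp),
                 Assay = do.call(rbind, assay) %||% NULL,
                 Subject = do.call(rbind, subj) %||% NULL,
                 Sample = samp_tb,
                 Group = do.call(rbind, grp),
                 Intervention = do.call(rbind, intv) %||% NULL,
                 Occurrence = NULL, Analysis = ana, Result = do.call(rbind, res) %||% NULL,
                 Material = mat_tb, Ontology = ont, Documentation = doc)
  reg <- build_default_registry()
  tables <- lapply(stats::setNames(names(reg$classes), names(reg$classes)),
                   function(cn) {
                     tb <- tables[[cn]]
                     if (is.null(tb)) return(empty_class_table(reg$classes[[cn]]))
                     conform_class_table(reg$classes[[cn]], tb)$table
                   })
  bundle <- record_bundle(tables = tables)
  structure(list(bundle = bundle, matrix = emat,
                 truth = list(planted_genes = planted,
                              responders = responders,
                              batch_samples = sort(batch_refs),
                              sample_meta = exps_meta),
                 config = cfg),
            class = "sea_simulation")
}

#' @export
print.sea_simulation <- function(x, ...) {
  cat(sprintf(paste0("synthetic simulation: %d studies, %d subjects, ",
                     "%d genes (%d planted), %d expsamples\n"),
              x$config$n_studies, length(unique(x$truth$sample_meta$subject)),
              x$config$n_genes, length(x$truth$planted_genes),
              nrow(x$truth$sample_meta)))
  invisible(x)
}

#' Emit a VIGET-shaped input (metadata table + expression CSV)
#'
#' One metadata row per experimental sample plus the genes-by-samples
#' matrix, the two-file layout used by the VIGET connector.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return Paths of `metadata.csv` and `expression.csv`.
#' @export
simulate_viget_files <- function(config, out_dir) {
  sim <- simulate_study(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- sim$truth$sample_meta
  subj <- sim$bundle$tables$Subject
  study <- sim$bundle$tables$Study
  md <- data.frame(
    study_accession = meta$study,
    study_title = study$name[match(meta$study, study$study_id)],
    subject_accession = meta$subject,
    species = subj$species[match(meta$subject, subj$subject_id)],
    sex = meta$sex,
    age = subj$age[match(meta$subject, subj$subject_id)],
    vaccine = meta$vaccine,
    vaccine_vo_id = meta$vo_id,
    study_time_collected = meta$day,
    geo_accession = meta$ref,
    biosample_accession = meta$biosample_ref,
    expsample_type = "PBMC",
    batch = ifelse(meta$ref %in% sim$truth$batch_samples, "true", "false"),
    stringsAsFactors = FALSE)
  p1 <- write_csv_plain(md, file.path(out_dir, "metadata.csv"))
  p2 <- write_expression_matrix(sim$matrix,
                                file.path(out_dir, "expression.csv"))
  invisible(c(p1, p2))
}

#' Emit an ImmPort-shaped directory of per-table CSVs
#'
#' The same synthetic content as [simulate_study()], laid out the way the
#' ImmPort relational dumps are: three intervention-type tables
#' (intervention / immune_exposure / treatment), three sample tables
#' (biosample / control_sample / expsample), study-level tables, and one
#' CSV per assay type.  Consolidating the directory with
#' [immport_to_bundle()] conserves all rows.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the vector of paths written.
#' @export
simulate_immport_tables <- function(config, out_dir) {
  sim <- simulate_study(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  b <- sim$bundle$tables
  paths <- character()
  wr <- function(df, name) {
    p <- write_csv_plain(df, file.path(out_dir, paste0(name, ".csv")))
    paths <<- c(paths, p)
  }
  wr(data.frame(study_accession = b$Study$study_id, name = b$Study$name,
                start_date = b$Study$start_date,
                stringsAsFactors = FALSE), "study")
  wr(data.frame(experiment_accession = b$Experiment$experiment_id,
                study_accession = b$Experiment$study_id,
                name = b$Experiment$name, stringsAsFactors = FALSE),
     "experiment")
  wr(data.frame(subject_accession = b$Subject$subject_id,
                experiment_accession = b$Subject$experiment_id,
                age_reported = b$Subject$age, gender = b$Subject$sex,
                species = b$Subject$species,
                stringsAsFactors = FALSE), "subject")

  iv <- b$Intervention
  iv_src <- data.frame(intervention_accession = iv$intervention_id,
                       subject_accession = iv$subject_id,
                       name_reported = iv$material,
                       material_vo_id = iv$material_ontology_id,
                       type_reported = iv$intervention_type,
                       dose_reported = iv$dose,
                       route_reported = iv$route,
                       start_day = iv$intervention_time,
                       stringsAsFactors = FALSE)
  split_idx <- (seq_len(nrow(iv_src)) - 1L) %% 3L
  wr(iv_src[split_idx == 0L, , drop = FALSE], "intervention")
  wr(iv_src[split_idx == 1L, , drop = FALSE], "immune_exposure")
  wr(iv_src[split_idx == 2L, , drop = FALSE], "treatment")

  sa <- b$Sample
  sa_src <- data.frame(sample_accession = sa$sample_id,
                       subject_accession = sa$subject_id,
                       collection_method = sa$collection,
                       study_time_collected = sa$collection_time,
                       biosample_source = sa$biosample_source,
                       subtype = sa$expsample_type,
                       biosample_accession = sa$biosample_reference_name,
                       expsample_accession = sa$expsample_reference_name,
                       batch = sa$batch,
                       stringsAsFactors = FALSE)
  wr(sa_src[sa$type == "biosample", , drop = FALSE], "biosample")
  wr(sa_src[sa$type == "control", , drop = FALSE], "control_sample")
  wr(sa_src[sa$type == "expsample", , drop = FALSE], "expsample")

  asy <- merge(b$Result, b$Assay, by = "assay_id")
  wr(data.frame(result_accession = asy$result_id,
                assay_accession = asy$assay_id,
                expsample_accession = asy$sample_id,
                experiment_accession = asy$experiment_id,
                datatype = asy$datatype, filetype = asy$filetype,
                reference_name = asy$reference_name,
                platform = asy$platform,
                stringsAsFactors = FALSE),
     "assay_gene_expression")
  invisible(paths)
}

#' Emit a CELLxGENE-shaped observation table
#'
#' One observation row per cell: the 10 common variables each paired with
#' an `_ontology_term_id` column, the two metadata columns (`sample_id`,
#' `observation_join_id`), and `extra_vars` author-specific columns.
#'
#' @param config A [sim_config()].
#' @param path Optional CSV path; when `NULL` the data frame is returned
#'   without writing.
#' @return The observation data frame (invisibly when written to `path`).
#' @export
simulate_cellxgene_obs <- function(config, path = NULL) {
  sim <- simulate_study(config)
  meta <- sim$truth$sample_meta
  n <- nrow(meta) * config$cells_per_sample
  idx <- rep(seq_len(nrow(meta)), each = config$cells_per_sample)
  k <- function(x) rep(x, length.out = n)
  obs <- data.frame(
    organism = k("Homo sapiens"),
    organism_ontology_term_id = k("NCBITaxon_9606"),
    species = k("Homo sapiens"),
    species_ontology_term_id = k("NCBITaxon_9606"),
    developmental_stage = k("human adult stage"),
    developmental_stage_ontology_term_id = k("HsapDv_0000087"),
    disease = k("influenza"), disease_ontology_term_id = k("MONDO_0005812"),
    sex = meta$sex[idx],
    sex_ontology_term_id = ifelse(meta$sex[idx] == "female",
                                  "PATO_0000383", "PATO_0000384"),
    tissue = k("blood"), tissue_ontology_term_id = k("UBERON_0000178"),
    cell_type = k("peripheral blood mononuclear cell"),
    cell_type_ontology_term_id = k("CL_2000001"),
    suspension = k("cell"), suspension_ontology_term_id = k(NA_character_),
    assay = k("10x 3' v3"), assay_ontology_term_id = k("EFO_0009922"),
    tissue_type = k("tissue"), tissue_type_ontology_term_id = k(NA_character_),
    sample_id = meta$ref[idx],
    observation_join_id = sprintf("OBS%06d", seq_len(n)),
    stringsAsFactors = FALSE, check.names = FALSE)
  if (config$extra_vars > 0) {
    extra <- with_seed(config$seed + 1L, {
      as.data.frame(stats::setNames(lapply(seq_len(config$extra_vars),
        function(j) round(stats::runif(n), 3)),
        sprintf("author_var_%02d", seq_len(config$extra_vars))))
    })
    obs <- cbind(obs, extra)
  }
  if (!is.null(path)) {
    write_csv_plain(obs, path)
    return(invisible(obs))
  }
  obs
}
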