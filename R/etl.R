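#' ETL connectors
#'
#' Three connectors convert heterogeneous source layouts into SEA CDM
#' record bundles: VIGET (a study/sample metadata table plus a normalized
#' log2 expression matrix), ImmPort (a directory of per-table relational
#' CSV dumps), and CELLxGENE (per-observation metadata from an H5ad file or
#' a flattened table).  All three are driven by mapping configurations; the
#' defaults shipped with the package are provisional column crosswalks
#' meant to be overridden for a concrete export.  Connectors prefix primary
#' and foreign keys (`VIGET:`, `IMMPORT:`, `CXG:`) so bundles from
#' different sources merge into one store without collisions, and route
#' unmapped source columns into the extended-attribute table instead of
#' failing.
#'
#' @name etl_connectors
NULL

#' Load a shipped default mapping configuration
#' @param source `"viget"`, `"immport"`, or `"cellxgene"`.
#' @return The parsed mapping configuration (a list).
#' @export
default_mapping <- function(source = c("viget", "immport", "cellxgene")) {
  source <- match.arg(source)
  yaml::read_yaml(system.file("extdata", "config",
                              paste0(source, "_mapping.yaml"),
                              package = "seacdm", mustWork = TRUE))
}

#' The fixed CELLxGENE common-variable map
#'
#' The 10 common observation variables and their target class/attribute in
#' the model (demographics to Subject, specimen fields to Sample, disease
#' to Occurrence, assay to Assay, cell type to Result).
#' @param config Optional mapping configuration; default shipped config.
#' @return Named list: source variable -> list(class, attribute).
#' @export
get_cellxgene_common_map <- function(config = NULL) {
  config <- config %||% default_mapping("cellxgene")
  config$common_variables
}

# rename + constant-fill helper: colmap is source_name -> target_name
map_table <- function(df, colmap, constants = NULL) {
  out <- df
  hit <- intersect(names(colmap), names(df))
  names(out)[match(hit, names(out))] <- unlist(colmap[hit])
  for (nm in names(constants %||% list())) {
    if (!nm %in% names(out)) out[[nm]] <- rep(constants[[nm]], nrow(out))
  }
  out
}

prefix_ids <- function(df, class_def, prefix) {
  idcols <- c(class_def$primary_key,
              vapply(class_def$foreign_keys, `[[`, "", "column"))
  for (cn in intersect(idcols, names(df))) {
    v <- as.character(df[[cn]])
    df[[cn]] <- ifelse(is_blank(v), NA, paste0(prefix, v))
  }
  df
}

# ---------------------------------------------------------------- VIGET --

#' Convert a VIGET-shaped input into a bundle and an expression matrix
#'
#' Builds Study / Experiment / Subject / Intervention / Sample / Assay
#' records from the per-sample metadata table, reads the expression matrix
#' keyed by the sample reference names, flags batch-affected samples, and
#' records the expression file location in a Documentation row.  Samples
#' present in only one of the two files produce warnings, not errors.
#'
#' @param metadata_path CSV with one row per experimental sample.
#' @param expression_path CSV expression matrix (`gene` column + one column
#'   per sample reference name).
#' @param config Mapping configuration; default [default_mapping()]`("viget")`.
#' @param registry Schema registry; default [build_default_registry()].
#' @return List with `bundle` (a `sea_bundle`) and `matrix`
#'   (an `expression_matrix`).
#' @export
viget_to_bundle <- function(metadata_path, expression_path, config = NULL,
                            registry = build_default_registry()) {
  config <- config %||% default_mapping("viget")
  pfx <- config$id_prefix %||% "VIGET:"
  cols <- config$columns
  md <- read_csv_strict(metadata_path)
  emat <- read_expression_matrix(expression_path)

  getcol <- function(role) {
    src <- cols[[role]]
    if (!is.null(src) && src %in% names(md)) {
      v <- as.character(md[[src]]); ifelse(is_blank(v), NA, v)
    } else rep(NA_character_, nrow(md))
  }
  if (nrow(md) == 0) {
    warning("VIGET metadata table is empty; returning an empty bundle")
    return(list(bundle = empty_bundle(registry), matrix = emat))
  }

  study <- getcol("study"); subject <- getcol("subject")
  ref <- getcol("expsample_ref")
  missing_in_matrix <- setdiff(stats::na.omit(ref), emat$samples)
  if (length(missing_in_matrix) > 0)
    warning(length(missing_in_matrix),
            " metadata sample(s) absent from the expression matrix, e.g. ",
            missing_in_matrix[1])
  extra_in_matrix <- setdiff(emat$samples, ref)
  if (length(extra_in_matrix) > 0)
    warning(length(extra_in_matrix),
            " matrix sample(s) absent from the metadata, e.g. ",
            extra_in_matrix[1])

  ustudy <- unique(stats::na.omit(study))
  study_tb <- data.frame(study_id = paste0(pfx, ustudy),
                         name = getcol("study_name")[match(ustudy, study)],
                         stringsAsFactors = FALSE)
  exp_tb <- data.frame(experiment_id = paste0(pfx, "EXP-", ustudy),
                       study_id = paste0(pfx, ustudy),
                       name = "immune response profiling",
                       stringsAsFactors = FALSE)
  usub <- unique(stats::na.omit(subject))
  first <- match(usub, subject)
  subj_tb <- data.frame(
    subject_id = paste0(pfx, usub),
    experiment_id = paste0(pfx, "EXP-", study[first]),
    age = suppressWarnings(as.numeric(getcol("age")[first])),
    sex = getcol("sex")[first],
    species = getcol("species")[first],
    stringsAsFactors = FALSE)
  vac <- getcol("vaccine"); vid <- getcol("vaccine_vo_id")
  uvac <- unique(stats::na.omit(vac))
  mat_tb <- data.frame(material_id = paste0(pfx, "MAT-", seq_along(uvac)),
                       name = uvac,
                       name_ontology_id = vid[match(uvac, vac)],
                       type = "vaccine", stringsAsFactors = FALSE)
  intv_tb <- data.frame(
    intervention_id = paste0(pfx, "INTV-", usub),
    subject_id = paste0(pfx, usub),
    material_id = mat_tb$material_id[match(vac[first], mat_tb$name)],
    intervention_type = "vaccination",
    material = vac[first],
    material_ontology_id = vid[first],
    intervention_time = 0, stringsAsFactors = FALSE)
  batch_raw <- tolower(getcol("batch"))
  samp_tb <- data.frame(
    sample_id = paste0(pfx, "ES-", ref),
    subject_id = paste0(pfx, subject),
    type = "expsample",
    collection = config$constants$collection %||% NA,
    collection_time = suppressWarnings(as.numeric(getcol("day"))),
    expsample_type = getcol("expsample_type"),
    biosample_reference_name = getcol("biosample_ref"),
    expsample_reference_name = ref,
    batch = ifelse(!is.na(batch_raw) &
                   batch_raw %in% c("true", "1", "yes", "y"), "true", NA),
    stringsAsFactors = FALSE)
  assay_tb <- data.frame(
    assay_id = paste0(pfx, "ASY-", ref),
    experiment_id = paste0(pfx, "EXP-", study),
    sample_id = paste0(pfx, "ES-", ref),
    assay_type = "transcription profiling assay",
    stringsAsFactors = FALSE)
  doc_tb <- data.frame(
    documentation_id = paste0(pfx, "DOC-1"),
    doc_type = "data file", path = as.character(expression_path),
    description = "normalized log2 gene expression matrix",
    target_class = "Study", target_id = study_tb$study_id[1],
    stringsAsFactors = FALSE)

  mapped_src <- unlist(cols)
  extra_cols <- setdiff(names(md), mapped_src)
  ext <- extended_from_extras("Sample", samp_tb$sample_id,
                              if (length(extra_cols))
                                md[, extra_cols, drop = FALSE] else NULL)

  tables <- list(Study = study_tb, Experiment = exp_tb, Subject = subj_tb,
                 Material = mat_tb, Intervention = intv_tb,
                 Sample = samp_tb, Assay = assay_tb,
                 Documentation = doc_tb)
  tables <- lapply(stats::setNames(names(tables), names(tables)), function(cn)
    conform_class_table(registry$classes[[cn]], tables[[cn]])$table)
  prov <- stats::setNames(rep(metadata_path, length(tables)), names(tables))
  bundle <- record_bundle(tables = tables, extended = ext, provenance = prov)

  flags <- stats::setNames(rep(FALSE, length(emat$samples)), emat$samples)
  flagged <- ref[!is.na(samp_tb$batch)]
  flags[intersect(flagged, names(flags))] <- TRUE
  emat <- expression_matrix(emat$values, batch_flag = flags)
  list(bundle = bundle, matrix = emat)
}

# -------------------------------------------------------------- ImmPort --

#' Consolidate an ImmPort-shaped directory of per-table CSVs
#'
#' Applies the model's merge rules: the three intervention-type tables
#' (Intervention, Immune Exposure, Treatment) concatenate into the single
#' Intervention class; the three sample tables (Biosample, Control Sample,
#' Expsample) concatenate into Sample with the controlled `type` column;
#' each assay-specific table splits into Assay rows plus one Result row per
#' source record.  The source table of every merged row is kept as a
#' `source_table` extended attribute.  Key collisions across merged source
#' tables are an error naming the tables involved.
#'
#' @param table_dir Directory of `<table>.csv` files.
#' @param config Mapping configuration; default
#'   [default_mapping()]`("immport")`.
#' @param registry Schema registry.
#' @return A `sea_bundle`.
#' @export
immport_to_bundle <- function(table_dir, config = NULL,
                              registry = build_default_registry()) {
  config <- config %||% default_mapping("immport")
  pfx <- config$id_prefix %||% "IMMPORT:"
  files <- list.files(table_dir, pattern = "\\.csv$", full.names = TRUE)
  tname <- sub("\\.csv$", "", basename(files))
  names(files) <- tname
  tables <- list()
  ext <- empty_extended()

  take <- function(class_name, df, colmap, src_table, constants = NULL) {
    cl <- registry$classes[[class_name]]
    mapped <- map_table(df, colmap, constants)
    conf <- conform_class_table(cl, mapped)
    tb <- prefix_ids(conf$table, cl, pfx)
    if (nrow(tb) > 0) {
      prov_rows <- data.frame(class = class_name,
                              record_id = as.character(tb[[cl$primary_key]]),
                              name = "source_table", value = src_table,
                              ontology_id = NA_character_,
                              stringsAsFactors = FALSE)
      unmapped <- setdiff(names(df), names(colmap))
      ext <<- rbind(ext, prov_rows,
                    extended_from_extras(class_name, tb[[cl$primary_key]],
                      if (length(unmapped)) df[, unmapped, drop = FALSE]
                      else NULL))
    }
    tables[[class_name]] <<- rbind(tables[[class_name]], tb)
    tb
  }

  claimed <- character()
  for (tn in names(config$tables %||% list())) {
    if (!tn %in% tname) next
    spec <- config$tables[[tn]]
    take(spec$class, read_csv_strict(files[[tn]]), spec$columns, tn)
    claimed <- c(claimed, tn)
  }

  merge_group <- function(src_tables, class_name, colmap, constants_fn) {
    seen_keys <- list()
    cl <- registry$classes[[class_name]]
    for (tn in src_tables) {
      if (!tn %in% tname) next
      df <- read_csv_strict(files[[tn]])
      tb <- take(class_name, df, colmap, tn, constants_fn(tn))
      keys <- as.character(tb[[cl$primary_key]])
      for (prev in names(seen_keys)) {
        clash <- intersect(keys, seen_keys[[prev]])
        if (length(clash) > 0)
          stop("key collision while merging '", tn, "' and '", prev,
               "' into ", class_name, ": ", clash[1])
      }
      seen_keys[[tn]] <- keys
      claimed <<- c(claimed, tn)
    }
  }
  merge_group(config$intervention_tables %||% character(), "Intervention",
              config$intervention_columns, function(tn) NULL)
  st <- config$sample_tables %||% list()
  merge_group(names(st), "Sample", config$sample_columns,
              function(tn) list(type = st[[tn]]))

  # assay-specific tables: Result per row, Assay per distinct accession
  assay_files <- setdiff(tname[startsWith(tname,
                                config$assay_table_prefix %||% "assay_")],
                         claimed)
  for (tn in assay_files) {
    df <- read_csv_strict(files[[tn]])
    atype <- gsub("_", " ", sub(paste0("^", config$assay_table_prefix), "",
                                tn))
    cmap <- config$assay_columns
    mapped <- map_table(df, cmap)
    if (!"assay_id" %in% names(mapped) ||
        all(is_blank(mapped[["assay_id"]]))) {
      sid <- mapped[["sample_id"]] %||% seq_len(nrow(mapped))
      mapped$assay_id <- if (nrow(mapped) > 0)
        paste0("ASY-", tn, "-", as.character(sid)) else character(0)
    }
    mapped$original_assay_type <- rep(atype, nrow(mapped))
    take("Result", mapped,
         stats::setNames(as.list(c("result_id", "assay_id", "datatype",
                                   "filetype", "reference_name",
                                   "original_assay_type")),
                         c("result_id", "assay_id", "datatype", "filetype",
                           "reference_name", "original_assay_type")),
         tn)
    adf <- mapped[!duplicated(mapped$assay_id), , drop = FALSE]
    adf$assay_type <- rep(atype, nrow(adf))
    take("Assay", adf,
         stats::setNames(as.list(c("assay_id", "sample_id", "experiment_id",
                                   "assay_type", "platform")),
                         c("assay_id", "sample_id", "experiment_id",
                           "assay_type", "platform")),
         tn)
    claimed <- c(claimed, tn)
  }

  skipped <- setdiff(tname, claimed)
  if (length(skipped) > 0)
    warning("unmapped source table(s) skipped: ",
            paste(skipped, collapse = ", "))
  prov <- stats::setNames(rep(table_dir, length(tables)), names(tables))
  record_bundle(tables = tables, extended = ext, provenance = prov)
}

# ------------------------------------------------------------ CELLxGENE --

#' Convert CELLxGENE-shaped observation metadata into a bundle
#'
#' Accepts either an H5ad file (only the `obs` observation frame is read)
#' or a pre-flattened CSV of observations.  The 10 common variables map to
#' their fixed targets — demographics to Subject, specimen fields to
#' Sample, disease to Occurrence, assay to Assay, cell type to a
#' per-observation Result — with each variable's companion ontology-ID
#' column filling the paired `_ontology_id` column.  A missing common
#' variable yields `NA` plus a warning; author-specific columns are routed
#' to extended attributes of the observation's Result record.
#'
#' @param source Path to `.h5ad` or `.csv`, or an observation data frame.
#' @param config Mapping configuration; default
#'   [default_mapping()]`("cellxgene")`.
#' @param registry Schema registry.
#' @return A `sea_bundle`.
#' @export
cellxgene_to_bundle <- function(source, config = NULL,
                                registry = build_default_registry()) {
  config <- config %||% default_mapping("cellxgene")
  pfx <- config$id_prefix %||% "CXG:"
  obs <- if (is.data.frame(source)) {
    source
  } else if (tolower(tools::file_ext(source)) == "h5ad") {
    read_h5ad_obs(source)
  } else {
    read_csv_strict(source)
  }
  src_label <- if (is.data.frame(source)) "data.frame" else source
  names(obs) <- gsub(" ", "_", names(obs))
  sid_col <- config$metadata$sample_id %||% "sample_id"
  if (!sid_col %in% names(obs))
    stop("observation table lacks the required '", sid_col, "' column")
  oid_col <- config$metadata$observation_join_id %||% "observation_join_id"
  n <- nrow(obs)
  obs_id <- if (oid_col %in% names(obs)) as.character(obs[[oid_col]])
            else sprintf("OBS%06d", seq_len(n))

  cmap <- config$common_variables
  pair_col <- function(var) {
    cands <- paste0(var, c("_ontology_term_id", "_ontology_id"))
    hit <- cands[cands %in% names(obs)]
    if (length(hit)) hit[1] else NA_character_
  }
  getvar <- function(var) {
    if (var %in% names(obs)) {
      v <- as.character(obs[[var]]); ifelse(is_blank(v), NA, v)
    } else {
      warning("common variable '", var, "' missing from ", src_label)
      rep(NA_character_, n)
    }
  }
  vals <- lapply(stats::setNames(names(cmap), names(cmap)), getvar)
  oids <- lapply(stats::setNames(names(cmap), names(cmap)), function(var) {
    pc <- pair_col(var)
    if (is.na(pc)) rep(NA_character_, n) else {
      v <- as.character(obs[[pc]]); ifelse(is_blank(v), NA, v)
    }
  })

  sid <- as.character(obs[[sid_col]])
  us <- unique(sid)
  first <- match(us, sid)
  pick <- function(var) vals[[var]][first]
  pick_oid <- function(var) oids[[var]][first]

  study_tb <- data.frame(study_id = paste0(pfx, "STUDY-1"),
                         name = config$dataset_name %||% "CELLxGENE import",
                         stringsAsFactors = FALSE)
  exp_tb <- data.frame(experiment_id = paste0(pfx, "EXP-1"),
                       study_id = study_tb$study_id,
                       name = "single-cell profiling",
                       stringsAsFactors = FALSE)
  subj_tb <- data.frame(
    subject_id = paste0(pfx, "SUBJ-", us),
    experiment_id = exp_tb$experiment_id,
    organism = pick("organism"), organism_ontology_id = pick_oid("organism"),
    species = pick("species"), species_ontology_id = pick_oid("species"),
    developmental_stage = pick("developmental_stage"),
    developmental_stage_ontology_id = pick_oid("developmental_stage"),
    sex = pick("sex"), sex_ontology_id = pick_oid("sex"),
    stringsAsFactors = FALSE)
  samp_tb <- data.frame(
    sample_id = paste0(pfx, "SAMP-", us),
    subject_id = subj_tb$subject_id,
    type = "expsample",
    expsample_reference_name = us,
    tissue = pick("tissue"), tissue_ontology_id = pick_oid("tissue"),
    tissue_type = pick("tissue_type"),
    tissue_type_ontology_id = pick_oid("tissue_type"),
    suspension = pick("suspension"),
    suspension_ontology_id = pick_oid("suspension"),
    stringsAsFactors = FALSE)
  has_disease <- !is.na(pick("disease"))
  occ_tb <- data.frame(
    occurrence_id = paste0(pfx, "OCC-", us),
    subject_id = subj_tb$subject_id,
    occurrence_type = "disease", disease = pick("disease"),
    disease_ontology_id = pick_oid("disease"),
    stringsAsFactors = FALSE)[has_disease, , drop = FALSE]
  assay_tb <- data.frame(
    assay_id = paste0(pfx, "ASY-", us),
    experiment_id = exp_tb$experiment_id,
    sample_id = samp_tb$sample_id,
    assay_type = pick("assay"), assay_type_ontology_id = pick_oid("assay"),
    stringsAsFactors = FALSE)
  res_tb <- data.frame(
    result_id = paste0(pfx, "RES-", obs_id),
    assay_id = paste0(pfx, "ASY-", sid),
    datatype = "cell annotation",
    reference_name = obs_id,
    cell_type = vals[["cell_type"]],
    cell_type_ontology_id = oids[["cell_type"]],
    stringsAsFactors = FALSE)

  mapped_src <- c(names(cmap), vapply(names(cmap), pair_col, ""),
                  sid_col, oid_col)
  extra_cols <- setdiff(names(obs), mapped_src)
  ext <- extended_from_extras("Result", res_tb$result_id,
                              if (length(extra_cols))
                                obs[, extra_cols, drop = FALSE] else NULL)

  tables <- list(Study = study_tb, Experiment = exp_tb, Subject = subj_tb,
                 Sample = samp_tb, Occurrence = occ_tb, Assay = assay_tb,
                 Result = res_tb)
  tables <- lapply(stats::setNames(names(tables), names(tables)), function(cn)
    conform_class_table(registry$classes[[cn]], tables[[cn]])$table)
  prov <- stats::setNames(rep(src_label, length(tables)), names(tables))
  record_bundle(tables = tables, extended = ext, provenance = prov)
}

#' Read the observation frame of an H5ad file
#'
#' Minimal reader for the AnnData on-disk format: the `obs` group is read
#' with rhdf5, categorical columns (codes + categories) are decoded, and
#' the stored column order is respected.  Requires the `rhdf5` package.
#'
#' @param path Path to an `.h5ad` file.
#' @return A data frame, one row per observation.
#' @export
read_h5ad_obs <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("reading .h5ad requires the rhdf5 package; ",
         "flatten the obs table to CSV instead")
  raw <- rhdf5::h5read(path, "obs", read.attributes = TRUE)
  attrs <- rhdf5::h5readAttributes(path, "obs")
  decode <- function(x) {
    if (is.list(x) && all(c("codes", "categories") %in% names(x))) {
      codes <- as.integer(x$codes)
      out <- as.character(x$categories)[ifelse(codes < 0, NA, codes + 1L)]
      return(out)
    }
    if (is.array(x)) x <- as.vector(x)
    x
  }
  cols <- lapply(raw, decode)
  cols <- cols[!vapply(cols, is.list, logical(1))]
  order_attr <- attrs[["column-order"]]
  idx_name <- attrs[["_index"]] %||% "_index"
  keep <- unique(c(intersect(as.character(order_attr %||% names(cols)),
                             names(cols)),
                   names(cols)))
  df <- as.data.frame(cols[keep], stringsAsFactors = FALSE,
                      check.names = FALSE)
  if (idx_name %in% names(df)) {
    names(df)[names(df) == idx_name] <- "observation_join_id"
  }
  df
}
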