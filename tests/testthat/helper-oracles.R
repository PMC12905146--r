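# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written as naive loops / library calls so they
# share no code path with the package implementation they check.

mini_vo_path <- function(ext = "csv") {
  system.file("extdata", "ontology", paste0("vo_mini_synthetic.", ext),
              package = "seacdm")
}

mini_vo <- function() load_ontology(mini_vo_path())

# Exhaustive per-gene / per-pair reimplementation of the stimulated-gene
# filter, scalar arithmetic only.
oracle_stimulated <- function(values, batch_flag, pairs, min_fc = 1,
                              floor_ = 0.2, min_subjects = 3,
                              exclude_batch = TRUE) {
  stim <- character()
  for (g in rownames(values)) {
    n_pass <- 0L
    for (i in seq_len(nrow(pairs))) {
      b <- pairs$baseline_ref[i]
      f <- pairs$followup_ref[i]
      if (exclude_batch && (isTRUE(batch_flag[[b]]) ||
                            isTRUE(batch_flag[[f]]))) next
      xb <- values[g, b]
      xf <- values[g, f]
      if ((xf - xb) >= min_fc && (xf >= floor_ || xb >= floor_))
        n_pass <- n_pass + 1L
    }
    if (n_pass >= min_subjects) stim <- c(stim, g)
  }
  stim
}

# Brute-force reimplementation of the four-way join + DISTINCT counts.
oracle_material_summary <- function(bundle, materials) {
  sa <- bundle$tables$Sample
  su <- bundle$tables$Subject
  iv <- bundle$tables$Intervention
  ex <- bundle$tables$Experiment
  bio <- character(); stu <- character(); exps <- character()
  for (i in seq_len(nrow(sa))) {
    subj <- sa$subject_id[i]
    if (is.na(subj)) next
    srow <- which(su$subject_id == subj)
    for (s in srow) {
      erow <- which(ex$experiment_id == su$experiment_id[s])
      ivrow <- which(iv$subject_id == subj &
                     !is.na(iv$material) & iv$material %in% materials)
      if (length(erow) == 0 || length(ivrow) == 0) next
      # cross join semantics: any matching intervention+experiment
      if (!is.na(sa$biosample_reference_name[i]))
        bio <- c(bio, sa$biosample_reference_name[i])
      if (!is.na(sa$expsample_reference_name[i]))
        exps <- c(exps, sa$expsample_reference_name[i])
      stu <- c(stu, ex$study_id[erow])
    }
  }
  list(n_biosamples = length(unique(bio)),
       n_studies = length(unique(stats::na.omit(stu))),
       n_expsamples = length(unique(exps)))
}

# igraph-based transitive closure (descendants of `term`), independent of
# the package's frontier expansion.
oracle_descendants <- function(graph, term, include_self = FALSE) {
  if (nrow(graph$edges) == 0) {
    return(if (include_self) term else character())
  }
  g <- igraph::graph_from_data_frame(graph$edges[, c("child", "parent")],
                                     vertices = graph$terms$id)
  out <- names(igraph::subcomponent(g, term, mode = "in"))
  if (!include_self) out <- setdiff(out, term)
  sort(out)
}

# Random DAG as an ontology term table (parents always earlier nodes).
random_dag <- function(n, seed, max_parents = 3) {
  withr::local_seed(seed)
  ids <- sprintf("T%04d", seq_len(n))
  parents <- vapply(seq_len(n), function(i) {
    if (i == 1) return("")
    k <- sample(0:min(max_parents, i - 1), 1)
    paste(sample(ids[seq_len(i - 1)], k), collapse = "|")
  }, character(1))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = ids, label = paste("term", ids),
                              parents = parents),
                   path, row.names = FALSE)
  load_ontology(path)
}

# Random referentially-closed mini bundle exercising the summary join:
# several studies/experiments, subjects with 0-2 interventions over a
# material pool, samples with occasionally missing reference names.
random_mini_bundle <- function(seed, registry, materials_pool = NULL) {
  withr::local_seed(seed)
  if (is.null(materials_pool)) {
    materials_pool <- data.frame(
      name = c("Fluarix", "Fluvirin", "Fluzone", "FluMist", "saline",
               "influenza", "Influenza A virus"),
      vo_id = c("VO_9100001", "VO_9100002", "VO_0000047", "VO_9100004",
                NA, NA, NA),
      stringsAsFactors = FALSE)
  }
  n_study <- sample(1:3, 1)
  n_subj <- sample(4:12, 1)
  study <- data.frame(study_id = sprintf("RS%02d", seq_len(n_study)),
                      name = "random study")
  exper <- data.frame(experiment_id = sprintf("RE%02d", seq_len(n_study)),
                      study_id = study$study_id, name = "random exp")
  subj <- data.frame(
    subject_id = sprintf("RSU%03d", seq_len(n_subj)),
    experiment_id = sample(exper$experiment_id, n_subj, replace = TRUE),
    sex = sample(c("female", "male"), n_subj, replace = TRUE),
    species = "Homo sapiens")
  ivs <- list(); mat_rows <- list(); k <- 0
  for (s in seq_len(n_subj)) {
    for (j in seq_len(sample(0:2, 1))) {
      k <- k + 1
      mi <- sample(nrow(materials_pool), 1)
      ivs[[k]] <- data.frame(
        intervention_id = sprintf("RIV%03d", k),
        subject_id = subj$subject_id[s],
        intervention_type = "vaccination",
        material = materials_pool$name[mi],
        material_ontology_id = materials_pool$vo_id[mi],
        intervention_time = 0)
    }
  }
  iv <- if (k > 0) do.call(rbind, ivs) else NULL
  used_mats <- unique(stats::na.omit(iv$material))
  mat <- data.frame(
    material_id = sprintf("RM%02d", seq_along(used_mats)),
    name = used_mats,
    name_ontology_id = materials_pool$vo_id[match(used_mats,
                                                  materials_pool$name)])
  samples <- list(); k <- 0
  for (s in seq_len(n_subj)) {
    for (j in seq_len(sample(1:4, 1))) {
      k <- k + 1
      type <- sample(c("biosample", "expsample", "control"), 1)
      samples[[k]] <- data.frame(
        sample_id = sprintf("RSA%04d", k),
        subject_id = subj$subject_id[s],
        type = type,
        collection_time = sample(c(0, 7, 14, 28), 1),
        biosample_reference_name =
          if (stats::runif(1) < 0.8) sprintf("RBR%04d", k) else NA,
        expsample_reference_name =
          if (type == "expsample") sprintf("RGSM%04d", k) else NA)
    }
  }
  tables <- list(Study = study, Experiment = exper, Subject = subj,
                 Intervention = iv, Material = mat,
                 Sample = do.call(rbind, samples))
  tables <- Filter(Negate(is.null), tables)
  tables <- lapply(stats::setNames(names(tables), names(tables)), function(cn)
    seacdm:::conform_class_table(registry$classes[[cn]], tables[[cn]])$table)
  record_bundle(tables = tables)
}

# Subject pairs straight from simulation truth, bypassing the SQL store.
pairs_from_truth <- function(sim, day, baseline_day = 0) {
  meta <- sim$truth$sample_meta
  out <- lapply(split(meta, meta$subject), function(m) {
    b <- sort(m$ref[m$day == baseline_day])
    f <- sort(m$ref[m$day == day])
    if (length(b) == 0 || length(f) == 0) return(NULL)
    data.frame(subject_id = m$subject[1], baseline_ref = b[1],
               followup_ref = f[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$subject_id), , drop = FALSE]
}

random_matrix <- function(seed, n_genes = 100, n_pairs = 12) {
  withr::local_seed(seed)
  refs <- c(sprintf("B%03d", seq_len(n_pairs)),
            sprintf("F%03d", seq_len(n_pairs)))
  vals <- matrix(stats::rnorm(n_genes * 2 * n_pairs, mean = 0.5, sd = 1),
                 nrow = n_genes,
                 dimnames = list(sprintf("G%04d", seq_len(n_genes)), refs))
  flags <- stats::setNames(stats::runif(2 * n_pairs) < 0.1, refs)
  pairs <- data.frame(subject_id = sprintf("S%03d", seq_len(n_pairs)),
                      baseline_ref = refs[seq_len(n_pairs)],
                      followup_ref = refs[n_pairs + seq_len(n_pairs)],
                      stringsAsFactors = FALSE)
  list(matrix = expression_matrix(vals, batch_flag = flags), pairs = pairs)
}
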