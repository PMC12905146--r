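#' Paired-sample querying and the stimulated-gene statistic
#'
#' The analysis payload: select, per subject, a baseline (day 0) and a
#' follow-up experimental sample for a given intervention material, then
#' call a gene *stimulated* when its log2 expression rises by at least
#' `min_log2_fc` (default 1, i.e. 2-fold) over baseline, with an expression
#' floor of `expr_floor_log2` (default 0.2) on at least one of the two
#' days, in at least `min_subjects` (default 3) subjects, after removing
#' batch-flagged samples.  All thresholds are inclusive.
#'
#' @name query_engine
NULL

#' Construct a sample query
#'
#' @param material Intervention material: either an exact name (e.g.
#'   `"Fluarix"`) or an ontology term id (e.g. `"VO_0001236"`); a term id
#'   combined with an ontology graph expands to all descendant materials.
#' @param day Follow-up day (days post-intervention, `>= 0`).
#' @param species Optional subject species filter (exact match).
#' @param sex Optional `"female"` or `"male"`.
#' @param baseline_day Baseline day, default 0; must be `< day`.
#' @return A `sample_query` list.
#' @export
sample_query <- function(material, day, species = NULL, sex = NULL,
                         baseline_day = 0) {
  if (day < 0) stop("day must be >= 0")
  if (baseline_day >= day) stop("baseline_day must be < day")
  if (!is.null(sex) && !sex %in% c("female", "male"))
    stop("sex must be 'female' or 'male'")
  structure(list(material = material, day = day, species = species,
                 sex = sex, baseline_day = baseline_day),
            class = "sample_query")
}

#' Construct gene filter criteria
#'
#' @param min_log2_fc Minimum log2 fold change day over baseline
#'   (inclusive; default 1 = 2-fold).
#' @param expr_floor_log2 Expression floor: the gene must reach this log2
#'   value on the follow-up day or at baseline (inclusive; default 0.2).
#' @param min_subjects Minimum number of subject pairs passing both filters
#'   for a gene to count as stimulated (default 3).
#' @param exclude_batch Remove batch-flagged samples before filtering
#'   (default `TRUE`).
#' @return A `gene_filter_criteria` list.
#' @export
gene_filter_criteria <- function(min_log2_fc = 1, expr_floor_log2 = 0.2,
                                 min_subjects = 3, exclude_batch = TRUE) {
  if (min_log2_fc <= 0) stop("min_log2_fc must be > 0")
  if (min_subjects < 1) stop("min_subjects must be >= 1")
  structure(list(min_log2_fc = min_log2_fc,
                 expr_floor_log2 = expr_floor_log2,
                 min_subjects = min_subjects,
                 exclude_batch = isTRUE(exclude_batch)),
            class = "gene_filter_criteria")
}

#' Select baseline/follow-up sample pairs from a store
#'
#' Retrieves, for every subject matching the query (intervention material,
#' optional species and sex), the experimental sample at the baseline day
#' and at the follow-up day; subjects lacking either are excluded.  When
#' `material` is an ontology term id and a graph is supplied, matching
#' expands over the term's descendants (self included): an intervention
#' matches if its material name is a descendant label or its
#' `material_ontology_id` is a descendant id.  A subject with several
#' samples at one day contributes the lexicographically first reference
#' name, with a warning.
#'
#' @param store A `sea_store`.
#' @param query A [sample_query()].
#' @param ontology Optional `ontology_graph` for term-id expansion.
#' @return Data frame with columns `subject_id`, `baseline_ref`,
#'   `followup_ref` (zero rows when nothing matches).
#' @export
select_pairs <- function(store, query, ontology = NULL) {
  mats <- query$material
  ids <- character()
  if (!is.null(ontology) && looks_like_curie(query$material) &&
      query$material %in% ontology$terms$id) {
    ids <- descendants(ontology, query$material, include_self = TRUE)
    labs <- id_to_label(ontology, ids)
    mats <- unique(stats::na.omit(labs))
  }
  conds <- c("sa.type = 'expsample'",
             "sa.expsample_reference_name IS NOT NULL",
             sprintf("sa.collection_time IN (%f, %f)",
                     query$baseline_day, query$day))
  params <- list()
  matcond <- sprintf("i.material IN (%s)",
                     paste(rep("?", length(mats)), collapse = ", "))
  params <- c(params, as.list(mats))
  if (length(ids) > 0) {
    matcond <- sprintf("(%s OR i.material_ontology_id IN (%s))", matcond,
                       paste(rep("?", length(ids)), collapse = ", "))
    params <- c(params, as.list(ids))
  }
  conds <- c(conds, matcond)
  if (!is.null(query$species)) {
    conds <- c(conds, "su.species = ?")
    params <- c(params, list(query$species))
  }
  if (!is.null(query$sex)) {
    conds <- c(conds, "su.sex = ?")
    params <- c(params, list(query$sex))
  }
  sql <- paste(
    "SELECT DISTINCT su.subject_id AS subject_id,",
    "       sa.collection_time AS day,",
    "       sa.expsample_reference_name AS ref",
    "FROM Sample sa",
    "JOIN Subject su ON sa.subject_id = su.subject_id",
    "JOIN Intervention i ON i.subject_id = su.subject_id",
    "WHERE", paste(conds, collapse = " AND "))
  hits <- DBI::dbGetQuery(store$con, sql, params = params)
  if (nrow(hits) == 0)
    return(data.frame(subject_id = character(), baseline_ref = character(),
                      followup_ref = character(), stringsAsFactors = FALSE))
  pick <- function(sub_hits, d) {
    refs <- sort(sub_hits$ref[sub_hits$day == d])
    if (length(refs) > 1)
      warning("subject ", sub_hits$subject_id[1], " has ", length(refs),
              " samples at day ", d, "; using ", refs[1])
    if (length(refs) == 0) NA_character_ else refs[1]
  }
  out <- do.call(rbind, lapply(split(hits, hits$subject_id), function(h) {
    data.frame(subject_id = h$subject_id[1],
               baseline_ref = pick(h, query$baseline_day),
               followup_ref = pick(h, query$day),
               stringsAsFactors = FALSE)
  }))
  out <- out[!is.na(out$baseline_ref) & !is.na(out$followup_ref), ,
             drop = FALSE]
  out <- out[order(out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute the stimulated-gene statistic over subject pairs
#'
#' For each gene and subject pair, the pair *passes* when the log2 change
#' (follow-up minus baseline) is at least `min_log2_fc` and the expression
#' reaches `expr_floor_log2` on at least one of the two days; a gene is
#' *stimulated* when at least `min_subjects` pairs pass.  When
#' `exclude_batch` is set, pairs touching a batch-flagged sample are
#' removed before filtering.  Both thresholds are inclusive.
#'
#' @param matrix An `expression_matrix` containing every pair's samples.
#' @param pairs Data frame from [select_pairs()] (columns `subject_id`,
#'   `baseline_ref`, `followup_ref`).
#' @param criteria A [gene_filter_criteria()].
#' @return A `stimulation_result`: `table` (gene, n_passing, mean log2
#'   change over passing pairs), `stimulated` (character vector of genes),
#'   plus the per-gene/pair `deltas` and `pass` matrices and the pairs
#'   actually used.
#' @export
stimulated_genes <- function(matrix, pairs, criteria = gene_filter_criteria()) {
  refs <- c(pairs$baseline_ref, pairs$followup_ref)
  missing <- setdiff(refs, matrix$samples)
  if (length(missing) > 0)
    stop("sample reference(s) not in expression matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  used <- pairs
  if (criteria$exclude_batch && nrow(used) > 0) {
    drop <- matrix$batch_flag[used$baseline_ref] |
            matrix$batch_flag[used$followup_ref]
    used <- used[!drop, , drop = FALSE]
  }
  ng <- length(matrix$genes)
  if (nrow(used) == 0) {
    deltas <- matrix(numeric(0), nrow = ng, ncol = 0,
                     dimnames = list(matrix$genes, NULL))
    pass <- matrix(logical(0), nrow = ng, ncol = 0,
                   dimnames = list(matrix$genes, NULL))
  } else {
    xb <- matrix$values[, used$baseline_ref, drop = FALSE]
    xd <- matrix$values[, used$followup_ref, drop = FALSE]
    deltas <- xd - xb
    pass <- (deltas >= criteria$min_log2_fc) &
            (xd >= criteria$expr_floor_log2 |
             xb >= criteria$expr_floor_log2)
    colnames(deltas) <- colnames(pass) <- used$subject_id
  }
  n_passing <- as.integer(rowSums(pass))
  mean_delta <- ifelse(n_passing > 0,
                       rowSums(deltas * pass) / n_passing, NA_real_)
  tab <- data.frame(gene = matrix$genes, n_passing = n_passing,
                    mean_delta = mean_delta,
                    stimulated = n_passing >= criteria$min_subjects,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 stimulated = tab$gene[tab$stimulated],
                 deltas = deltas, pass = pass, pairs = used,
                 criteria = criteria),
            class = "stimulation_result")
}

#' @export
print.stimulation_result <- function(x, ...) {
  cat(sprintf(paste0("stimulated-gene result: %d / %d genes stimulated ",
                     "(>= %g log2 FC, floor %g, >= %d subjects, %d pairs)\n"),
              length(x$stimulated), nrow(x$table),
              x$criteria$min_log2_fc, x$criteria$expr_floor_log2,
              x$criteria$min_subjects, nrow(x$pairs)))
  invisible(x)
}

#' Group per-vaccine gene sets by ontology vaccine class
#'
#' Each class term's gene set is the union of the gene sets of vaccines
#' whose term is a descendant of the class (self included) — e.g. grouping
#' trivalent inactivated vaccines versus live attenuated ones.  Vaccines
#' whose name resolves to no listed class are reported via the
#' `"unassigned"` attribute with a warning.
#'
#' @param gene_lists Named list: vaccine name -> character vector of genes.
#' @param ontology An `ontology_graph`.
#' @param classes Character vector of class term ids; names, if given, name
#'   the output.
#' @return Named list: class -> union gene set, with attribute
#'   `"unassigned"`.
#' @export
group_by_vaccine_class <- function(gene_lists, ontology, classes) {
  out_names <- names(classes) %||% classes
  vac_ids <- vapply(names(gene_lists), function(v) {
    label_to_id(ontology, v) %||% NA_character_
  }, character(1))
  assigned <- character()
  out <- lapply(seq_along(classes), function(i) {
    members <- names(gene_lists)[!is.na(vac_ids) &
      vac_ids %in% descendants(ontology, classes[i], include_self = TRUE)]
    assigned <<- union(assigned, members)
    sort(unique(unlist(gene_lists[members], use.names = FALSE)))
  })
  names(out) <- out_names
  unassigned <- setdiff(names(gene_lists), assigned)
  if (length(unassigned) > 0)
    warning("vaccine(s) not under any listed class: ",
            paste(unassigned, collapse = ", "))
  attr(out, "unassigned") <- unassigned
  out
}

#' Membership-region counts over named sets (Venn regions)
#'
#' Counts every one of the `2^k - 1` exclusive membership regions of `k`
#' named sets; region names join set names with `&`.  Region counts sum to
#' the size of the union.
#'
#' @param sets Named list of character vectors.
#' @return Named integer vector over all non-empty membership regions
#'   (zero counts included).
#' @export
overlap_counts <- function(sets) {
  k <- length(sets)
  stopifnot(k >= 1, !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1)
  region_names <- function(mask) paste(names(sets)[mask], collapse = "&")
  masks <- lapply(seq_len(2^k - 1), function(i) as.logical(bitwAnd(
    i, 2^(seq_len(k) - 1)) > 0))
  counts <- stats::setNames(integer(length(masks)),
                            vapply(masks, region_names, ""))
  if (length(universe) > 0) {
    sig <- apply(memb, 1, function(r) region_names(r))
    tb <- table(sig)
    counts[names(tb)] <- as.integer(tb)
  }
  counts
}

#' Export a stimulation result as CSV or JSON
#'
#' Writes one row per stimulated gene (symbol, number of passing subjects,
#' mean log2 change), the list format accepted by downstream enrichment
#' services.  The JSON form also records the criteria used and validates
#' against the schema shipped with the package.
#'
#' @param result A `stimulation_result`.
#' @param format `"csv"` or `"json"`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_results <- function(result, format = c("csv", "json"), path) {
  format <- match.arg(format)
  tab <- result$table[result$table$stimulated,
                      c("gene", "n_passing", "mean_delta"), drop = FALSE]
  rownames(tab) <- NULL
  if (format == "csv") {
    write_csv_plain(tab, path)
  } else {
    payload <- list(criteria = result$criteria[c("min_log2_fc",
                                                 "expr_floor_log2",
                                                 "min_subjects",
                                                 "exclude_batch")],
                    genes = tab)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}

#' Read back an exported gene list
#' @param path Path written by [export_results()].
#' @return Data frame with columns gene, n_passing, mean_delta.
#' @export
read_results <- function(path) {
  if (tolower(tools::file_ext(path)) == "json") {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    tab <- payload$genes
    if (length(tab) == 0)
      tab <- data.frame(gene = character(), n_passing = integer(),
                        mean_delta = numeric(), stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  tab$n_passing <- as.integer(tab$n_passing)
  tab$mean_delta <- as.numeric(tab$mean_delta)
  rownames(tab) <- NULL
  tab
}

#' Check an exported JSON gene list against the shipped schema
#'
#' Structural validation of the required fields and types declared in
#' `extdata/schema/stimulation_result_schema.json`.
#'
#' @param path Path to a JSON file written by [export_results()].
#' @return `TRUE` invisibly, or an error describing the first problem.
#' @export
validate_results_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  cr <- payload$criteria
  if (is.null(cr)) stop("missing 'criteria'")
  for (f in c("min_log2_fc", "expr_floor_log2", "min_subjects",
              "exclude_batch"))
    if (is.null(cr[[f]])) stop("criteria missing '", f, "'")
  if (!is.numeric(cr$min_log2_fc) || cr$min_log2_fc <= 0)
    stop("criteria$min_log2_fc must be a positive number")
  if (!is.logical(cr$exclude_batch))
    stop("criteria$exclude_batch must be a boolean")
  genes <- payload$genes
  if (is.null(genes)) stop("missing 'genes'")
  for (g in genes) {
    for (f in c("gene", "n_passing", "mean_delta"))
      if (is.null(g[[f]])) stop("gene entry missing '", f, "'")
    if (!is.character(g$gene)) stop("gene symbol must be a string")
    if (!is.numeric(g$n_passing) || g$n_passing < 0 ||
        g$n_passing != round(g$n_passing))
      stop("n_passing must be a non-negative integer")
    if (!is.numeric(g$mean_delta)) stop("mean_delta must be a number")
  }
  invisible(TRUE)
}
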