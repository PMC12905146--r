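#' Relational store
#'
#' A `sea_store` materializes a registry in an embedded SQL database
#' (SQLite) — one table per class plus the `extended_attribute` side table —
#' and serves the model's summary and sample-selection queries.  The same
#' DDL is available in a MySQL dialect via [emit_ddl()] for deployment on a
#' server; the embedded engine keeps everything desk-scale and testable.
#'
#' @name sea_store
NULL

#' Initialize a relational store
#'
#' Creates (if absent) all schema tables in an embedded SQLite database.
#' Re-initializing an existing store is a no-op: tables are created
#' `IF NOT EXISTS` and data are never dropped.
#'
#' @param registry A `sea_registry`.
#' @param target `":memory:"` (default) or a file path for a persistent
#'   database.
#' @return A `sea_store` handle wrapping the DBI connection.
#' @export
init_store <- function(registry, target = ":memory:") {
  if (!is.character(target) || length(target) != 1 || is.na(target))
    stop("invalid store target")
  if (target != ":memory:" && !dir.exists(dirname(target)))
    stop("invalid store target: directory does not exist: ", dirname(target))
  con <- DBI::dbConnect(RSQLite::SQLite(), target)
  for (stmt in strsplit(emit_ddl(registry, "portable"), ";\\s*\\n")[[1]]) {
    stmt <- trimws(stmt)
    if (nzchar(stmt)) DBI::dbExecute(con, stmt)
  }
  structure(list(con = con, registry = registry, target = target,
                 dialect = "portable"),
            class = "sea_store")
}

#' Close a store handle
#' @param store A `sea_store`.
#' @export
close_store <- function(store) {
  DBI::dbDisconnect(store$con)
  invisible(NULL)
}

#' @export
print.sea_store <- function(x, ...) {
  cat(sprintf("SEA CDM store (%s), %d tables\n", x$target,
              length(DBI::dbListTables(x$con))))
  invisible(x)
}

#' Load a bundle into a store
#'
#' Validates the bundle first and rejects it before any write when
#' referential integrity fails (load is atomic).  Loading is append-only;
#' a primary key already present in the store is an error naming the class
#' and the key.
#'
#' @param store A `sea_store`.
#' @param bundle A `sea_bundle`.
#' @return Named integer vector of rows loaded per table (including
#'   `extended_attribute`).
#' @export
load_bundle <- function(store, bundle) {
  reg <- store$registry
  rep <- validate_bundle(reg, bundle)
  if (!rep$ok) {
    stop("bundle failed validation (", nrow(rep$violations),
         " violation(s)); first: ", rep$violations$message[1])
  }
  # duplicate-key check against existing contents, before any write
  for (cn in intersect(names(bundle$tables), names(reg$classes))) {
    tb <- bundle$tables[[cn]]
    if (is.null(tb) || nrow(tb) == 0) next
    pk <- reg$classes[[cn]]$primary_key
    existing <- DBI::dbGetQuery(store$con,
      sprintf('SELECT "%s" AS pk FROM "%s"', pk, cn))$pk
    clash <- intersect(as.character(tb[[pk]]), as.character(existing))
    if (length(clash) > 0)
      stop("duplicate primary key in class ", cn, ": ", clash[1])
  }
  report <- integer()
  DBI::dbWithTransaction(store$con, {
    for (cn in names(reg$classes)) {
      tb <- bundle$tables[[cn]]
      n <- if (is.null(tb)) 0L else nrow(tb)
      if (n > 0) {
        tb <- conform_class_table(reg$classes[[cn]], tb)$table
        DBI::dbAppendTable(store$con, cn, tb)
      }
      report[cn] <- n
    }
    if (nrow(bundle$extended) > 0)
      DBI::dbAppendTable(store$con, "extended_attribute", bundle$extended)
    report["extended_attribute"] <- nrow(bundle$extended)
  })
  report
}

#' Dump a store back into a bundle
#'
#' Inverse of [load_bundle()] up to row order: reads every class table and
#' the extended-attribute table back into typed data frames.
#'
#' @param store A `sea_store`.
#' @return A `sea_bundle`.
#' @export
dump_bundle <- function(store) {
  reg <- store$registry
  tables <- lapply(reg$classes, function(cl) {
    df <- DBI::dbReadTable(store$con, cl$name, check.names = FALSE)
    conform_class_table(cl, df)$table
  })
  ext <- DBI::dbReadTable(store$con, "extended_attribute", check.names = FALSE)
  ext[] <- lapply(ext, function(x) ifelse(is_blank(x), NA, as.character(x)))
  prov <- rep(store$target, length(tables))
  names(prov) <- names(tables)
  record_bundle(tables = tables, extended = ext, provenance = prov)
}

#' Count studies and samples mentioning given intervention materials
#'
#' The model's canonical competency query — "how many studies, biosamples,
#' and experimental samples involve these materials?" — implemented as the
#' four-way join of Sample, Subject, Intervention, and Experiment with
#' DISTINCT counts of biosample reference names, study ids, and expsample
#' reference names.  Material matching is by exact (case-sensitive) string
#' against `Intervention.material`; ontology-aware expansion belongs to
#' [select_pairs()].
#'
#' @param store A `sea_store`.
#' @param materials Character vector of material names (the SQL `IN` list).
#' @return A list with `n_biosamples`, `n_studies`, `n_expsamples`.
#' @export
material_summary <- function(store, materials) {
  if (length(materials) == 0)
    return(list(n_biosamples = 0L, n_studies = 0L, n_expsamples = 0L))
  ph <- paste(rep("?", length(materials)), collapse = ", ")
  sql <- sprintf(paste(
    "SELECT COUNT(DISTINCT biosample_reference_name) AS n_biosamples,",
    "       COUNT(DISTINCT study_id) AS n_studies,",
    "       COUNT(DISTINCT expsample_reference_name) AS n_expsamples",
    "FROM Sample sa",
    "JOIN Subject su ON sa.subject_id = su.subject_id",
    "JOIN Intervention i ON i.subject_id = su.subject_id",
    "JOIN Experiment e ON e.experiment_id = su.experiment_id",
    "WHERE i.material IN (%s)"), ph)
  res <- DBI::dbGetQuery(store$con, sql, params = as.list(materials))
  list(n_biosamples = as.integer(res$n_biosamples),
       n_studies = as.integer(res$n_studies),
       n_expsamples = as.integer(res$n_expsamples))
}

#' Row counts per table in a store
#' @param store A `sea_store`.
#' @return Named integer vector.
#' @export
store_counts <- function(store) {
  tabs <- DBI::dbListTables(store$con)
  counts <- vapply(tabs, function(t) {
    as.integer(DBI::dbGetQuery(store$con,
      sprintf('SELECT COUNT(*) AS n FROM "%s"', t))$n)
  }, integer(1))
  counts
}
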