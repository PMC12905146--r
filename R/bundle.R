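#' Record bundles
#'
#' A `sea_bundle` is the in-memory form of one or more studies: a named list
#' of per-class data frames (`tables`), plus a long-format `extended` table
#' for source columns that have no schema attribute, and a `provenance` map
#' recording where each table came from.  Columns are typed by the schema:
#' `number` attributes are numeric, everything else character, with `NA`
#' meaning "no value" (serialized as the empty string in CSV).
#'
#' @param tables Named list of data frames, keyed by registry class names.
#' @param extended Data frame with columns class, record_id, name, value,
#'   ontology_id (zero rows if none).
#' @param provenance Named character vector, class name -> source path or
#'   `"synthetic"`.
#' @return A `sea_bundle` object.
#' @export
record_bundle <- function(tables = list(), extended = NULL, provenance = NULL) {
  if (is.null(extended)) extended <- empty_extended()
  if (is.null(provenance)) {
    provenance <- rep("synthetic", length(tables))
    names(provenance) <- names(tables)
  }
  structure(list(tables = tables, extended = extended,
                 provenance = provenance),
            class = "sea_bundle")
}

empty_extended <- function() {
  data.frame(class = character(), record_id = character(),
             name = character(), value = character(),
             ontology_id = character(), stringsAsFactors = FALSE)
}

#' Create an empty bundle with one zero-row table per registry class
#' @param registry A `sea_registry`.
#' @return A `sea_bundle` whose tables all have the schema columns and no rows.
#' @export
empty_bundle <- function(registry) {
  tables <- lapply(registry$classes, function(cl) empty_class_table(cl))
  record_bundle(tables = tables)
}

empty_class_table <- function(class_def) {
  cols <- class_columns(class_def)
  num <- class_numeric_columns(class_def)
  df <- as.data.frame(
    stats::setNames(lapply(cols, function(cn) {
      if (cn %in% num) numeric() else character()
    }), cols),
    stringsAsFactors = FALSE, check.names = FALSE)
  df
}

# Coerce a record table to the schema's column set and types; unknown
# columns are split off.  Returns list(table, extra) where extra holds the
# unknown columns (still aligned row-wise).
conform_class_table <- function(class_def, df) {
  cols <- class_columns(class_def)
  known <- intersect(names(df), cols)
  extra <- setdiff(names(df), cols)
  out <- empty_class_table(class_def)
  if (nrow(df) > 0) {
    out <- as.data.frame(stats::setNames(lapply(cols, function(cn) {
      v <- if (cn %in% known) df[[cn]] else rep(NA, nrow(df))
      if (cn %in% class_numeric_columns(class_def)) {
        suppressWarnings(as.numeric(ifelse(is_blank(v), NA, as.character(v))))
      } else {
        v <- as.character(v)
        ifelse(is_blank(v), NA_character_, v)
      }
    }), cols), stringsAsFactors = FALSE, check.names = FALSE)
  }
  extra_df <- if (length(extra) > 0) df[, extra, drop = FALSE] else NULL
  list(table = out, extra = extra_df)
}

# Route unknown columns of a source table into long-format extended rows.
# Paired `<name>_ontology_id` columns among the extras are folded into the
# ontology_id field of their base attribute's row.
extended_from_extras <- function(class_name, record_ids, extra_df) {
  if (is.null(extra_df) || ncol(extra_df) == 0 || nrow(extra_df) == 0)
    return(empty_extended())
  nms <- names(extra_df)
  pair_of <- function(nm) paste0(nm, "_ontology_id")
  bases <- nms[!(nms %in% pair_of(nms))]
  # an `_ontology_id` column without its base is kept as its own attribute
  rows <- list()
  for (nm in bases) {
    val <- as.character(extra_df[[nm]])
    oid <- if (pair_of(nm) %in% nms) as.character(extra_df[[pair_of(nm)]])
           else rep(NA_character_, length(val))
    keep <- !is_blank(val) | !is_blank(oid)
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      class = class_name, record_id = as.character(record_ids)[keep],
      name = nm, value = ifelse(is_blank(val), NA, val)[keep],
      ontology_id = ifelse(is_blank(oid), NA, oid)[keep],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty_extended())
  do.call(rbind, rows)
}

#' Merge bundles with disjoint identifier namespaces
#'
#' Concatenates the per-class tables of several bundles (e.g. one per source
#' connector).  Primary keys must not collide across inputs; connectors
#' prefix their identifiers (`VIGET:`, `IMMPORT:`, `CXG:`) to guarantee this.
#' @param ... `sea_bundle` objects.
#' @param registry A `sea_registry` used to locate primary keys.
#' @return A single merged `sea_bundle`.
#' @export
merge_bundles <- function(..., registry) {
  bundles <- list(...)
  tables <- list()
  prov <- character()
  for (b in bundles) {
    for (cn in names(b$tables)) {
      if (is.null(tables[[cn]])) {
        tables[[cn]] <- b$tables[[cn]]
      } else {
        tables[[cn]] <- rbind(tables[[cn]], b$tables[[cn]])
      }
      prov[cn] <- paste(unique(c(strsplit(prov[cn] %||% "", ";")[[1]],
                                 b$provenance[[cn]] %||% "synthetic")),
                        collapse = ";")
      prov[cn] <- sub("^;", "", prov[cn])
    }
  }
  for (cn in names(tables)) {
    cl <- registry$classes[[cn]]
    if (!is.null(cl) && anyDuplicated(tables[[cn]][[cl$primary_key]]))
      stop("primary-key collision in class ", cn, " while merging bundles")
  }
  ext <- do.call(rbind, c(lapply(bundles, `[[`, "extended"),
                          list(empty_extended())))
  record_bundle(tables = tables, extended = ext, provenance = prov)
}

#' @export
print.sea_bundle <- function(x, ...) {
  cat("SEA CDM record bundle\n")
  for (cn in names(x$tables))
    cat(sprintf("  %-14s %5d rows\n", cn, nrow(x$tables[[cn]])))
  if (nrow(x$extended) > 0)
    cat(sprintf("  extended attributes: %d rows\n", nrow(x$extended)))
  invisible(x)
}

# Total record count across tables (used in reports).
bundle_sizes <- function(bundle) {
  vapply(bundle$tables, nrow, integer(1))
}
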