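#' Validation reports
#'
#' Record- and bundle-level checks return a `validation_report`: `ok` is
#' `TRUE` exactly when the `violations` table is empty.  Violations carry
#' the class, the 1-based row index (NA for record-level checks without a
#' table context), a stable rule id, and a human-readable message.
#'
#' Rule ids: `missing_required`, `unknown_field`, `orphan_ontology_id`
#' (a `<attr>_ontology_id` has a value but the attribute itself is empty),
#' `controlled_value`, `duplicate_primary_key`, `dangling_fk`,
#' `dangling_link` (polymorphic Documentation/Ontology target),
#' `unknown_table`.
#'
#' @name validation_report
NULL

new_validation_report <- function(violations = NULL) {
  if (is.null(violations) || nrow(violations) == 0) {
    violations <- data.frame(class = character(), row = integer(),
                             rule = character(), message = character(),
                             stringsAsFactors = FALSE)
  }
  structure(list(ok = nrow(violations) == 0, violations = violations),
            class = "validation_report")
}

violation <- function(class, row, rule, message) {
  data.frame(class = class, row = as.integer(row), rule = rule,
             message = message, stringsAsFactors = FALSE)
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) {
    cat("validation OK (no violations)\n")
  } else {
    cat(sprintf("validation FAILED: %d violation(s)\n", nrow(x$violations)))
    print(utils::head(x$violations, 20))
    if (nrow(x$violations) > 20) cat("  ...\n")
  }
  invisible(x)
}

#' Validate a single record against its class definition
#'
#' Checks required fields, unknown fields (accepted when `extended = TRUE`,
#' mirroring the extended-attribute routing used by the connectors),
#' ontology-ID pairing (an identifier without a value is malformed), and
#' controlled-vocabulary domains such as `Sample$type`.
#'
#' @param registry A `sea_registry`.
#' @param class_name Name of the class the record claims to be.
#' @param record Named list or single-row data frame of field -> value.
#' @param extended If `TRUE` (default), fields outside the schema are legal
#'   (they would be routed to the extended-attribute table); if `FALSE`
#'   they are reported as `unknown_field` violations.
#' @param row Row index recorded in violations (default `NA`).
#' @return A `validation_report`.
#' @export
validate_record <- function(registry, class_name, record, extended = TRUE,
                            row = NA_integer_) {
  cl <- registry$classes[[class_name]]
  if (is.null(cl))
    stop("unknown class '", class_name, "' (not in registry)")
  if (is.data.frame(record)) record <- as.list(record)
  cols <- class_columns(cl)
  v <- list()

  for (a in cl$attributes) {
    if (a$required && blank1(record[[a$name]]))
      v[[length(v) + 1L]] <- violation(class_name, row, "missing_required",
        sprintf("required field '%s' is empty", a$name))
    if (a$ontology_pair) {
      pair <- paste0(a$name, "_ontology_id")
      if (!blank1(record[[pair]]) && blank1(record[[a$name]]))
        v[[length(v) + 1L]] <- violation(class_name, row, "orphan_ontology_id",
          sprintf("'%s' has an ontology ID but '%s' has no value", pair, a$name))
    }
    if (!is.null(a$values) && !blank1(record[[a$name]]) &&
        !(as.character(record[[a$name]][[1]]) %in% a$values))
      v[[length(v) + 1L]] <- violation(class_name, row, "controlled_value",
        sprintf("'%s' value '%s' outside {%s}", a$name,
                record[[a$name]][[1]], paste(a$values, collapse = ", ")))
  }
  if (!extended) {
    unknown <- setdiff(names(record), cols)
    for (u in unknown)
      v[[length(v) + 1L]] <- violation(class_name, row, "unknown_field",
        sprintf("field '%s' is not defined for class %s", u, class_name))
  }
  new_validation_report(if (length(v)) do.call(rbind, v))
}

#' Validate a bundle: per-record rules plus referential integrity
#'
#' Runs [validate_record()] over every row, enforces primary-key uniqueness
#' within each table, resolves every foreign-key value against the target
#' table's key set (dangling references are reported with their source row),
#' and checks the polymorphic `(target_class, target_id)` links of the
#' Documentation and Ontology accessory classes.
#'
#' @param registry A `sea_registry`.
#' @param bundle A `sea_bundle`.
#' @return A `validation_report`.
#' @export
validate_bundle <- function(registry, bundle) {
  v <- list()
  tables <- bundle$tables
  unknown_tables <- setdiff(names(tables), names(registry$classes))
  for (u in unknown_tables)
    v[[length(v) + 1L]] <- violation(u, NA, "unknown_table",
      sprintf("table '%s' does not correspond to a registry class", u))

  pk_index <- lapply(names(registry$classes), function(cn) {
    tb <- tables[[cn]]
    cl <- registry$classes[[cn]]
    if (is.null(tb) || nrow(tb) == 0) character() else
      as.character(tb[[cl$primary_key]])
  })
  names(pk_index) <- names(registry$classes)

  for (cn in intersect(names(tables), names(registry$classes))) {
    tb <- tables[[cn]]
    cl <- registry$classes[[cn]]
    if (is.null(tb) || nrow(tb) == 0) next
    for (i in seq_len(nrow(tb))) {
      rep_i <- validate_record(registry, cn, tb[i, , drop = FALSE],
                               extended = TRUE, row = i)
      if (!rep_i$ok) v[[length(v) + 1L]] <- rep_i$violations
    }
    dup <- duplicated(pk_index[[cn]])
    for (i in which(dup))
      v[[length(v) + 1L]] <- violation(cn, i, "duplicate_primary_key",
        sprintf("duplicate %s '%s'", cl$primary_key, pk_index[[cn]][i]))
    for (fk in cl$foreign_keys) {
      vals <- as.character(tb[[fk$column]])
      bad <- which(!is_blank(vals) & !(vals %in% pk_index[[fk$target_class]]))
      for (i in bad)
        v[[length(v) + 1L]] <- violation(cn, i, "dangling_fk",
          sprintf("%s '%s' not found in %s", fk$column, vals[i],
                  fk$target_class))
    }
    # polymorphic accessory links
    if (all(c("target_class", "target_id") %in% names(tb))) {
      tc <- as.character(tb$target_class); ti <- as.character(tb$target_id)
      for (i in seq_len(nrow(tb))) {
        if (is_blank(tc[i]) || is_blank(ti[i])) next
        if (!tc[i] %in% names(registry$classes)) {
          v[[length(v) + 1L]] <- violation(cn, i, "dangling_link",
            sprintf("target_class '%s' is not a registry class", tc[i]))
        } else if (!ti[i] %in% pk_index[[tc[i]]]) {
          v[[length(v) + 1L]] <- violation(cn, i, "dangling_link",
            sprintf("target_id '%s' not found in %s", ti[i], tc[i]))
        }
      }
    }
  }
  new_validation_report(if (length(v)) do.call(rbind, v))
}
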