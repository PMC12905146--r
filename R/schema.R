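#' SEA CDM schema registry
#'
#' The Study-Experiment-Assay common data model (SEA CDM) describes a
#' biomedical study as a set of interlinked classes: a study includes one or
#' more experiments, experiments enroll subjects and generate samples, and
#' assays run on samples produce results.  The registry holds the class
#' definitions (attributes, foreign keys, core/accessory flag, ontological
#' category) and the relation graph between classes, and is the single
#' source of truth for validation, template emission, DDL generation, the
#' relational store, and the knowledge-graph export.
#'
#' @name sea_registry
#' @keywords internal
NULL

new_attribute_def <- function(name, kind = "text", ontology_pair = FALSE,
                              required = FALSE, values = NULL,
                              provisional = FALSE) {
  kinds <- c("text", "number", "date", "identifier", "controlled")
  if (!kind %in% kinds)
    stop("unknown attribute kind '", kind, "' for attribute '", name, "'")
  structure(
    list(name = name, kind = kind, ontology_pair = isTRUE(ontology_pair),
         required = isTRUE(required), values = values,
         provisional = isTRUE(provisional)),
    class = "sea_attribute_def"
  )
}

new_class_def <- function(name, kind, category, primary_key, attributes,
                          foreign_keys = list()) {
  stopifnot(kind %in% c("core", "accessory"),
            category %in% c("process", "material_entity", "data_item"))
  attr_names <- vapply(attributes, `[[`, "", "name")
  if (anyDuplicated(attr_names))
    stop("duplicate attribute names in class ", name)
  structure(
    list(name = name, kind = kind, category = category,
         primary_key = primary_key, attributes = attributes,
         foreign_keys = foreign_keys),
    class = "sea_class_def"
  )
}

#' Build the default SEA CDM schema registry
#'
#' Loads the schema definition shipped with the package: 13 classes, of
#' which 10 are core (Study, Experiment, Assay, Subject, Sample, Group,
#' Intervention, Occurrence, Analysis, Result) and 3 accessory (Material,
#' Ontology, Documentation).  Every attribute flagged with an ontology pair
#' owns a companion `<attribute>_ontology_id` column so that values can be
#' standardized against ontology terms (e.g. a `sex` of "female" next to its
#' PATO identifier).
#'
#' @param schema_file Path to a schema YAML file; defaults to the definition
#'   installed with the package.
#' @return A `sea_registry` object: a list with `classes` (named list of
#'   class definitions) and `relations` (data frame of foreign-key edges).
#' @examples
#' reg <- build_default_registry()
#' length(reg$classes)              # 13
#' sea_class_names(reg, "core")     # the 10 core classes
#' @export
build_default_registry <- function(schema_file = NULL) {
  if (is.null(schema_file)) {
    schema_file <- system.file("extdata", "schema", "sea_cdm_schema.yaml",
                               package = "seacdm", mustWork = TRUE)
  }
  spec <- yaml::read_yaml(schema_file)
  classes <- lapply(names(spec$classes), function(cn) {
    cl <- spec$classes[[cn]]
    atts <- c(
      list(new_attribute_def(cl$primary_key, kind = "identifier",
                             required = TRUE)),
      lapply(cl$attributes, function(a) {
        new_attribute_def(a$name, kind = a$kind %||% "text",
                          ontology_pair = a$ontology_pair %||% FALSE,
                          required = a$required %||% FALSE,
                          values = a$values,
                          provisional = a$provisional %||% FALSE)
      })
    )
    fks <- lapply(cl$foreign_keys %||% list(), function(f) {
      structure(list(column = f$column, target_class = f$target_class,
                     target_column = f$target_column),
                class = "sea_foreign_key_def")
    })
    new_class_def(cn, cl$kind, cl$category, cl$primary_key, atts, fks)
  })
  names(classes) <- names(spec$classes)
  reg <- structure(list(classes = classes), class = "sea_registry")
  reg$relations <- registry_relations(reg)
  check_registry(reg)
  reg
}

registry_relations <- function(reg) {
  rows <- list()
  for (cl in reg$classes) {
    for (fk in cl$foreign_keys) {
      rows[[length(rows) + 1L]] <- data.frame(
        source = cl$name, column = fk$column, target = fk$target_class,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(source = character(), column = character(),
                      target = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

check_registry <- function(reg) {
  for (cl in reg$classes) {
    for (fk in cl$foreign_keys) {
      tgt <- reg$classes[[fk$target_class]]
      if (is.null(tgt))
        stop("class ", cl$name, ": FK target class '", fk$target_class,
             "' not in registry")
      if (!identical(fk$target_column, tgt$primary_key))
        stop("class ", cl$name, ": FK ", fk$column,
             " must reference the primary key of ", fk$target_class)
    }
  }
  invisible(reg)
}

#' Class names in a registry
#'
#' @param registry A `sea_registry`.
#' @param kind `"all"`, `"core"`, or `"accessory"`.
#' @return Character vector of class names.
#' @export
sea_class_names <- function(registry, kind = c("all", "core", "accessory")) {
  kind <- match.arg(kind)
  nm <- names(registry$classes)
  if (kind == "all") return(nm)
  nm[vapply(registry$classes, function(cl) cl$kind == kind, logical(1))]
}

# All physical columns of a class table, in template order:
# primary key first, then FKs, then each attribute followed immediately by
# its `_ontology_id` pair when present.
class_columns <- function(class_def) {
  cols <- class_def$primary_key
  cols <- c(cols, vapply(class_def$foreign_keys, `[[`, "", "column"))
  for (a in class_def$attributes) {
    if (a$name == class_def$primary_key) next
    cols <- c(cols, a$name)
    if (a$ontology_pair) cols <- c(cols, paste0(a$name, "_ontology_id"))
  }
  unique(cols)
}

# Columns that hold numbers (for typed round-tripping through CSV and SQL).
class_numeric_columns <- function(class_def) {
  vapply(Filter(function(a) a$kind == "number", class_def$attributes),
         `[[`, "", "name")
}

#' @export
print.sea_registry <- function(x, ...) {
  core <- sea_class_names(x, "core")
  acc <- sea_class_names(x, "accessory")
  cat("SEA CDM schema registry\n")
  cat(sprintf("  %d classes: %d core, %d accessory\n",
              length(x$classes), length(core), length(acc)))
  cat("  core:     ", paste(core, collapse = ", "), "\n")
  cat("  accessory:", paste(acc, collapse = ", "), "\n")
  cat(sprintf("  %d foreign-key relations\n", nrow(x$relations)))
  invisible(x)
}

#' @export
print.sea_class_def <- function(x, ...) {
  cat(sprintf("<%s class '%s' (%s), pk=%s>\n", x$kind, x$name, x$category,
              x$primary_key))
  for (a in x$attributes) {
    cat(sprintf("  %s [%s]%s%s\n", a$name, a$kind,
                if (a$ontology_pair) " +ontology_id" else "",
                if (a$provisional) " (provisional)" else ""))
  }
  for (f in x$foreign_keys)
    cat(sprintf("  FK %s -> %s.%s\n", f$column, f$target_class, f$target_column))
  invisible(x)
}
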