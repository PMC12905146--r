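#' Write per-class CSV templates
#'
#' Emits one CSV per class, header-only: the primary key, the foreign keys,
#' and each attribute immediately followed by its `<attribute>_ontology_id`
#' column where the schema declares an ontology pair.  New entries are
#' filled in as new rows; the files round-trip through [read_bundle()].
#'
#' @param registry A `sea_registry`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of paths written (one per class).
#' @export
write_templates <- function(registry, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(registry$classes, function(cl) {
    path <- file.path(out_dir, paste0(cl$name, ".csv"))
    write_csv_plain(empty_class_table(cl), path)
  }, character(1))
  invisible(unname(paths))
}

#' Read a directory of class CSVs into a bundle
#'
#' Files are matched to registry classes by name (`<Class>.csv`); an
#' `extended_attribute.csv` side file, if present, is loaded into the
#' bundle's extended table.  Empty strings become `NA`; columns not in the
#' schema are routed to extended attributes keyed by the row's primary key.
#' A CSV whose name is not a registry class is an error.
#'
#' @param registry A `sea_registry`.
#' @param dir Directory containing zero or more class CSVs.
#' @param validate If `TRUE` (default) attach a [validate_bundle()] report
#'   as attribute `"report"`.
#' @return A `sea_bundle`.
#' @export
read_bundle <- function(registry, dir, validate = TRUE) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  tables <- list()
  prov <- character()
  ext <- empty_extended()
  for (f in files) {
    cn <- sub("\\.csv$", "", basename(f))
    if (cn == "extended_attribute") {
      raw <- read_csv_strict(f)
      need <- c("class", "record_id", "name", "value", "ontology_id")
      if (!all(need %in% names(raw)))
        stop("extended_attribute.csv must have columns: ",
             paste(need, collapse = ", "))
      raw <- raw[, need, drop = FALSE]
      raw[] <- lapply(raw, function(x) ifelse(is_blank(x), NA, as.character(x)))
      ext <- rbind(ext, raw)
      next
    }
    if (!cn %in% names(registry$classes))
      stop("file '", basename(f), "' does not match any registry class")
    raw <- read_csv_strict(f)
    cl <- registry$classes[[cn]]
    conf <- conform_class_table(cl, raw)
    tables[[cn]] <- conf$table
    prov[cn] <- f
    if (!is.null(conf$extra)) {
      ext <- rbind(ext, extended_from_extras(cn, raw[[cl$primary_key]],
                                             conf$extra))
    }
  }
  b <- record_bundle(tables = tables, extended = ext, provenance = prov)
  if (validate) attr(b, "report") <- validate_bundle(registry, b)
  b
}

#' Write a bundle as per-class CSVs
#'
#' Inverse of [read_bundle()] up to column order and empty/`NA`
#' normalization.  Every registry class is written (header-only when the
#' bundle has no rows for it); extended attributes go to the long-format
#' `extended_attribute.csv` side table.
#'
#' @param registry A `sea_registry`.
#' @param bundle A `sea_bundle`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_bundle <- function(registry, bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (cl in registry$classes) {
    tb <- bundle$tables[[cl$name]]
    if (is.null(tb)) tb <- empty_class_table(cl)
    tb <- conform_class_table(cl, tb)$table
    paths <- c(paths, write_csv_plain(
      tb, file.path(out_dir, paste0(cl$name, ".csv"))))
  }
  if (nrow(bundle$extended) > 0) {
    paths <- c(paths, write_csv_plain(
      bundle$extended, file.path(out_dir, "extended_attribute.csv")))
  }
  invisible(paths)
}
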