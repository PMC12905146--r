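#' Emit SQL DDL for a schema registry
#'
#' Generates `CREATE TABLE IF NOT EXISTS` statements for every class plus
#' the `extended_attribute` side table (so re-running the script is safe).
#' Each ontology-paired attribute yields two columns; foreign keys are
#' declared as constraints.  The `portable` dialect uses only TEXT/REAL and
#' loads into SQLite; the `mysql` dialect uses backquoted identifiers,
#' VARCHAR keys, and InnoDB, matching a conventional MySQL deployment.
#'
#' @param registry A `sea_registry`.
#' @param dialect `"portable"` or `"mysql"`.
#' @return A single character string of SQL text (one statement per table).
#' @export
emit_ddl <- function(registry, dialect = c("portable", "mysql")) {
  dialect <- match.arg(dialect)
  # quote identifiers in both dialects (Group is a SQL reserved word)
  q <- if (dialect == "mysql") function(x) paste0("`", x, "`")
       else function(x) paste0('"', x, '"')
  sqltype <- function(kind) {
    if (kind == "number") {
      if (dialect == "mysql") "DOUBLE" else "REAL"
    } else if (kind == "identifier" && dialect == "mysql") {
      "VARCHAR(255)"
    } else if (dialect == "mysql") "TEXT" else "TEXT"
  }
  tail_clause <- if (dialect == "mysql") " ENGINE=InnoDB" else ""

  stmts <- vapply(registry$classes, function(cl) {
    defs <- character()
    num <- class_numeric_columns(cl)
    for (cn in class_columns(cl)) {
      kind <- if (cn == cl$primary_key) "identifier"
              else if (cn %in% num) "number"
              else if (cn %in% vapply(cl$foreign_keys, `[[`, "", "column"))
                "identifier"
              else "text"
      col <- paste0(q(cn), " ", sqltype(kind))
      if (cn == cl$primary_key) col <- paste0(col, " PRIMARY KEY")
      defs <- c(defs, col)
    }
    for (fk in cl$foreign_keys) {
      defs <- c(defs, sprintf("FOREIGN KEY (%s) REFERENCES %s(%s)",
                              q(fk$column), q(fk$target_class),
                              q(fk$target_column)))
    }
    sprintf("CREATE TABLE IF NOT EXISTS %s (\n  %s\n)%s;",
            q(cl$name), paste(defs, collapse = ",\n  "), tail_clause)
  }, character(1))

  ext <- sprintf(paste0(
    "CREATE TABLE IF NOT EXISTS %s (\n",
    "  %s TEXT,\n  %s %s,\n  %s TEXT,\n  %s TEXT,\n  %s TEXT\n)%s;"),
    q("extended_attribute"), q("class"), q("record_id"),
    if (dialect == "mysql") "VARCHAR(255)" else "TEXT",
    q("name"), q("value"), q("ontology_id"), tail_clause)

  paste(c(stmts, ext), collapse = "\n\n")
}
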