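#' Property-graph export
#'
#' Builds an in-memory property graph from a record bundle plus an
#' ontology: one node per record (labelled by its class) and one per
#' ontology term, with edges for every non-null foreign key, every
#' subClassOf assertion, and an `instance_of_term` edge wherever a record's
#' `*_ontology_id` value matches a loaded term.  The graph answers the
#' class-to-instances traversal ("all Materials under 'trivalent influenza
#' vaccine'") and exports to graph-database-loadable forms; no graph
#' server is required.
#'
#' @name kg_export
NULL

record_node_id <- function(class_name, pk) paste0(class_name, "/", pk)

#' Build a property graph from a bundle and an ontology
#'
#' @param bundle A validated `sea_bundle`.
#' @param ontology An `ontology_graph` (may be empty).
#' @param registry Schema registry.
#' @return A `sea_kg`: `nodes` (named list id -> list(label, properties))
#'   and `edges` (data frame source, target, relation).
#' @export
build_graph <- function(bundle, ontology = NULL,
                        registry = build_default_registry()) {
  nodes <- list()
  edges <- list()
  add_edge <- function(s, t, rel) {
    edges[[length(edges) + 1L]] <<- data.frame(
      source = s, target = t, relation = rel, stringsAsFactors = FALSE)
  }
  term_ids <- if (is.null(ontology)) character() else ontology$terms$id

  for (cn in intersect(names(bundle$tables), names(registry$classes))) {
    tb <- bundle$tables[[cn]]
    if (is.null(tb) || nrow(tb) == 0) next
    cl <- registry$classes[[cn]]
    pk <- as.character(tb[[cl$primary_key]])
    fk_cols <- vapply(cl$foreign_keys, `[[`, "", "column")
    for (i in seq_len(nrow(tb))) {
      props <- as.list(tb[i, , drop = FALSE])
      props <- props[!vapply(props, blank1, logical(1))]
      nid <- record_node_id(cn, pk[i])
      nodes[[nid]] <- list(label = cn, properties = props)
      for (j in seq_along(fk_cols)) {
        v <- tb[[fk_cols[j]]][i]
        if (!blank1(v))
          add_edge(nid, record_node_id(cl$foreign_keys[[j]]$target_class,
                                       as.character(v)),
                   fk_cols[j])
      }
      if (!blank1(props$target_class %||% NULL) &&
          !blank1(props$target_id %||% NULL))
        add_edge(nid, record_node_id(as.character(props$target_class),
                                     as.character(props$target_id)),
                 "about")
      oid_cols <- grep("_ontology_id$", names(tb), value = TRUE)
      for (oc in oid_cols) {
        v <- tb[[oc]][i]
        if (!blank1(v) && as.character(v) %in% term_ids)
          add_edge(nid, as.character(v), "instance_of_term")
      }
    }
  }
  if (!is.null(ontology)) {
    for (i in seq_len(nrow(ontology$terms))) {
      tid <- ontology$terms$id[i]
      nodes[[tid]] <- list(label = "OntologyTerm", properties = list(
        id = tid, name = ontology$terms$label[i],
        uri = paste0("http://purl.obolibrary.org/obo/", tid)))
    }
    for (i in seq_len(nrow(ontology$edges)))
      add_edge(ontology$edges$child[i], ontology$edges$parent[i],
               "subClassOf")
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), target = character(),
               relation = character(), stringsAsFactors = FALSE)
  # drop edges to nodes that do not exist (e.g. polymorphic link targets
  # outside the bundle); FK edges are guaranteed by prior validation
  keep <- edges$target %in% names(nodes) & edges$source %in% names(nodes)
  edges <- edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "sea_kg")
}

#' @export
print.sea_kg <- function(x, ...) {
  cat(sprintf("property graph: %d nodes, %d edges\n", length(x$nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Material nodes under an ontology term
#'
#' All Material nodes linked (via `instance_of_term`) to the term or any
#' transitive descendant — the Cypher `subClassOf*` traversal (zero or
#' more hops, so instances of the term itself count).
#'
#' @param graph A `sea_kg`.
#' @param term_id Ontology term id (must be a node).
#' @return Character vector of Material node ids.
#' @export
materials_under <- function(graph, term_id) {
  if (!term_id %in% names(graph$nodes) ||
      graph$nodes[[term_id]]$label != "OntologyTerm")
    stop("unknown ontology term node: ", term_id)
  sub_edges <- graph$edges[graph$edges$relation == "subClassOf", ,
                           drop = FALSE]
  kids <- split(sub_edges$source, sub_edges$target)
  closure <- term_id
  frontier <- term_id
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(kids[frontier], use.names = FALSE)),
                   closure)
    closure <- c(closure, nxt)
    frontier <- nxt
  }
  inst <- graph$edges[graph$edges$relation == "instance_of_term" &
                      graph$edges$target %in% closure, , drop = FALSE]
  mats <- unique(inst$source)
  mats[vapply(mats, function(n) graph$nodes[[n]]$label == "Material",
              logical(1))]
}

#' Full property map of one node
#' @param graph A `sea_kg`.
#' @param node_id Node id (`<Class>/<pk>` for records, the term id for
#'   ontology terms).
#' @return A list with `id`, `label`, `properties`.
#' @export
node_detail <- function(graph, node_id) {
  nd <- graph$nodes[[node_id]]
  if (is.null(nd)) stop("unknown node: ", node_id)
  list(id = node_id, label = nd$label, properties = nd$properties)
}

#' Export a graph for a graph database
#'
#' `node_edge_tables` writes Neo4j bulk-import-compatible CSVs
#' (`nodes.csv` with `:ID` and `:LABEL`, `edges.csv` with `:START_ID`,
#' `:END_ID`, `:TYPE`; property columns are the union over nodes, empty
#' where absent).  `cypher_script` writes one `MERGE` statement per node
#' and per edge, executable in any Cypher shell.
#'
#' @param graph A `sea_kg`.
#' @param format `"node_edge_tables"` or `"cypher_script"`.
#' @param out_dir Output directory.
#' @return Character vector of paths written.
#' @export
export_graph <- function(graph, format = c("node_edge_tables",
                                           "cypher_script"), out_dir) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(graph$nodes)
  if (format == "node_edge_tables") {
    prop_cols <- unique(unlist(lapply(graph$nodes, function(n)
      names(n$properties))))
    rows <- lapply(ids, function(nid) {
      n <- graph$nodes[[nid]]
      vals <- vapply(prop_cols, function(p) {
        v <- n$properties[[p]]
        if (blank1(v)) "" else as.character(v)
      }, character(1))
      c(`:ID` = nid, `:LABEL` = n$label, vals)
    })
    ndf <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE,
                         check.names = FALSE)
    if (length(ids) == 0)
      ndf <- stats::setNames(
        data.frame(matrix(character(), ncol = 2 + length(prop_cols))),
        c(":ID", ":LABEL", prop_cols))
    edf <- data.frame(`:START_ID` = graph$edges$source,
                      `:END_ID` = graph$edges$target,
                      `:TYPE` = graph$edges$relation,
                      stringsAsFactors = FALSE, check.names = FALSE)
    p1 <- write_csv_plain(ndf, file.path(out_dir, "nodes.csv"))
    p2 <- write_csv_plain(edf, file.path(out_dir, "edges.csv"))
    c(p1, p2)
  } else {
    esc <- function(x) gsub("'", "\\\\'", as.character(x))
    node_lines <- vapply(ids, function(nid) {
      n <- graph$nodes[[nid]]
      props <- n$properties[!vapply(n$properties, blank1, logical(1))]
      propstr <- paste(
        sprintf("`%s`: '%s'", names(props), vapply(props, esc, "")),
        collapse = ", ")
      sprintf("MERGE (n:`%s` {`_id`: '%s'%s});", n$label, esc(nid),
              if (nzchar(propstr)) paste0(", ", propstr) else "")
    }, character(1))
    edge_lines <- if (nrow(graph$edges) > 0) vapply(
      seq_len(nrow(graph$edges)), function(i) {
        sprintf(paste0("MATCH (a {`_id`: '%s'}), (b {`_id`: '%s'}) ",
                       "MERGE (a)-[:`%s`]->(b);"),
                esc(graph$edges$source[i]), esc(graph$edges$target[i]),
                graph$edges$relation[i])
      }, character(1)) else character()
    path <- file.path(out_dir, "graph.cypher")
    writeLines(c(node_lines, edge_lines), path)
    path
  }
}
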