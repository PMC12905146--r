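#' Ontology term graphs
#'
#' An `ontology_graph` holds terms (CURIE-style ids such as `VO_0001236`
#' with labels) and child-to-parent `subClassOf` edges, and answers the
#' transitive queries that drive ontology-aware selection: "all terms under
#' 'trivalent influenza vaccine'" expands a class to its specific vaccines.
#' Only the subClassOf backbone is modeled; no OWL reasoning is attempted.
#'
#' @name ontology_graph
NULL

new_ontology_graph <- function(terms, edges) {
  # terms: data.frame(id, label); edges: data.frame(child, parent)
  structure(list(terms = terms, edges = edges,
                 children = split(edges$child, edges$parent)),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology graph: %d terms, %d subClassOf edges\n",
              nrow(x$terms), nrow(x$edges)))
  invisible(x)
}

#' Load an ontology from a term table or an RDF/XML subset
#'
#' Two loaders share one output. A 3-column CSV term table
#' (`id`, `label`, `parents`, the last `|`-separated) covers fixtures and
#' hand-curated subsets; an RDF/XML file (e.g. an OWL export) is read
#' restricted to named classes and their `rdfs:subClassOf` assertions, with
#' ids compacted to CURIEs.  Every subClassOf assertion becomes a
#' child-to-parent edge; multiple parents are kept (the hierarchy is a DAG).
#' A cycle over subClassOf is an error listing the cycle; a parent id that
#' is never declared as a term is recorded as a bare term with a warning.
#'
#' @param source Path to a `.csv` term table or an RDF/XML (`.owl`, `.rdf`,
#'   `.xml`) file.
#' @return An `ontology_graph`.
#' @export
load_ontology <- function(source) {
  ext <- tolower(tools::file_ext(source))
  if (ext %in% c("owl", "rdf", "xml")) {
    parsed <- parse_rdf_subclassof(source)
  } else {
    parsed <- parse_term_table(source)
  }
  terms <- parsed$terms
  edges <- parsed$edges
  dangling <- setdiff(edges$parent, terms$id)
  if (length(dangling) > 0) {
    warning("parent term(s) not declared, added without labels: ",
            paste(dangling, collapse = ", "))
    terms <- rbind(terms, data.frame(id = dangling,
                                     label = NA_character_,
                                     stringsAsFactors = FALSE))
  }
  g <- new_ontology_graph(terms, edges)
  cyc <- find_cycle(g)
  if (!is.null(cyc))
    stop("subClassOf cycle detected: ", paste(cyc, collapse = " -> "))
  g
}

parse_term_table <- function(path) {
  if (!file.exists(path)) stop("ontology source not found: ", path)
  if (length(readLines(path, n = 1, warn = FALSE)) == 0) {
    return(list(terms = data.frame(id = character(), label = character(),
                                   stringsAsFactors = FALSE),
                edges = data.frame(child = character(), parent = character(),
                                   stringsAsFactors = FALSE)))
  }
  df <- read_csv_strict(path)
  need <- c("id", "label")
  if (!all(need %in% names(df)))
    stop("term table must have columns id, label[, parents]: ", path)
  if (anyDuplicated(df$id))
    stop("duplicate term id(s) in ", path, ": ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  terms <- data.frame(id = df$id, label = ifelse(is_blank(df$label), NA,
                                                 df$label),
                      stringsAsFactors = FALSE)
  edges <- list()
  if ("parents" %in% names(df)) {
    for (i in seq_len(nrow(df))) {
      ps <- strsplit(df$parents[i] %||% "", "\\|")[[1]]
      ps <- trimws(ps[!is_blank(ps)])
      if (length(ps) > 0)
        edges[[length(edges) + 1L]] <- data.frame(child = df$id[i],
                                                  parent = ps,
                                                  stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(child = character(), parent = character(),
               stringsAsFactors = FALSE)
  list(terms = terms, edges = edges)
}

# Restricted RDF/XML reader: named classes (rdf:about) with rdfs:label and
# rdfs:subClassOf rdf:resource=... . Anonymous restriction superclasses are
# skipped; URIs compact to the CURIE after the last '#' or '/'.
parse_rdf_subclassof <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
          rdfs = "http://www.w3.org/2000/01/rdf-schema#",
          owl = "http://www.w3.org/2002/07/owl#")
  curie <- function(uri) sub(".*[#/]", "", uri)
  nodes <- xml2::xml_find_all(doc, "//owl:Class[@rdf:about] | //rdf:Description[@rdf:about]", ns)
  terms <- list(); edges <- list()
  for (nd in nodes) {
    id <- curie(xml2::xml_attr(nd, "rdf:about", ns))
    lab <- xml2::xml_text(xml2::xml_find_first(nd, "./rdfs:label", ns))
    if (is.na(lab) || !nzchar(lab)) lab <- NA_character_
    terms[[length(terms) + 1L]] <- data.frame(id = id, label = lab,
                                              stringsAsFactors = FALSE)
    sup <- xml2::xml_find_all(nd, "./rdfs:subClassOf[@rdf:resource]", ns)
    for (s in sup) {
      edges[[length(edges) + 1L]] <- data.frame(
        child = id, parent = curie(xml2::xml_attr(s, "rdf:resource", ns)),
        stringsAsFactors = FALSE)
    }
  }
  terms <- if (length(terms)) do.call(rbind, terms) else
    data.frame(id = character(), label = character(), stringsAsFactors = FALSE)
  # collapse duplicate declarations, preferring a labeled one
  if (nrow(terms) > 0) {
    terms <- terms[order(terms$id, is.na(terms$label)), , drop = FALSE]
    terms <- terms[!duplicated(terms$id), , drop = FALSE]
    rownames(terms) <- NULL
  }
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(child = character(), parent = character(),
               stringsAsFactors = FALSE)
  list(terms = terms, edges = edges)
}

# Kahn's algorithm; returns NULL when acyclic, else one cycle as id path.
find_cycle <- function(graph) {
  edges <- graph$edges
  if (nrow(edges) == 0) return(NULL)
  ids <- graph$terms$id
  indeg <- stats::setNames(integer(length(ids)), ids)
  tb <- table(edges$parent)
  indeg[names(tb)] <- as.integer(tb)
  # edges point child -> parent; treat parent as depending on child
  queue <- names(indeg)[indeg == 0]
  seen <- 0L
  adj <- split(edges$parent, edges$child)
  while (length(queue) > 0) {
    u <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (p in adj[[u]] %||% character()) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen == length(ids)) return(NULL)
  # walk inside the residual subgraph to extract a concrete cycle
  resid <- names(indeg)[indeg > 0]
  start <- resid[1]
  path <- start; cur <- start
  repeat {
    nxt <- intersect(adj[[cur]] %||% character(), resid)[1]
    if (is.na(nxt)) return(resid)  # fallback: report the residual set
    if (nxt %in% path) return(c(path[which(path == nxt):length(path)], nxt))
    path <- c(path, nxt); cur <- nxt
  }
}

#' Transitive descendants of a term
#'
#' Closure over subClassOf edges, matching SPARQL `rdfs:subClassOf+`
#' semantics when `include_self = FALSE` and the Cypher `subClassOf*`
#' (zero-or-more hops) semantics when `include_self = TRUE`.
#'
#' @param graph An `ontology_graph`.
#' @param term_id Term identifier (must be loaded).
#' @param include_self Include `term_id` itself in the result?
#' @return Character vector of term ids (possibly empty).
#' @export
descendants <- function(graph, term_id, include_self = FALSE) {
  if (!term_id %in% graph$terms$id)
    stop("unknown term: ", term_id)
  out <- character()
  frontier <- term_id
  while (length(frontier) > 0) {
    kids <- unique(unlist(graph$children[frontier], use.names = FALSE))
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out <- setdiff(out, term_id)
  if (include_self) out <- c(term_id, out)
  unname(out)
}

#' Look up a term id by label
#'
#' Exact, case-insensitive match.  If several terms share a label the
#' lexicographically lowest id wins, with a warning.
#'
#' @param graph An `ontology_graph`.
#' @param label Term label.
#' @return The term id, or `NULL` when no term carries the label.
#' @export
label_to_id <- function(graph, label) {
  hit <- graph$terms$id[!is.na(graph$terms$label) &
                        tolower(graph$terms$label) == tolower(label)]
  if (length(hit) == 0) return(NULL)
  if (length(hit) > 1) {
    hit <- sort(hit)
    warning("label '", label, "' is ambiguous (", paste(hit, collapse = ", "),
            "); returning ", hit[1])
  }
  hit[1]
}

#' Label of a term id (NA when unlabeled/unknown)
#' @param graph An `ontology_graph`.
#' @param term_id Term identifier(s).
#' @return Character vector of labels.
#' @export
id_to_label <- function(graph, term_id) {
  graph$terms$label[match(term_id, graph$terms$id)]
}
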