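reg <- build_default_registry()

empty_graphs <- function() {
  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  load_ontology(empty)
}

test_that("graph construction counts nodes and edges exactly", {
  g0 <- build_graph(empty_bundle(reg), empty_graphs(), reg)
  expect_length(g0$nodes, 0)
  expect_equal(nrow(g0$edges), 0)

  sim <- simulate_study(sim_config(seed = 51, n_studies = 2,
                                   subjects_per_study = 2, days = c(0, 7)))
  onto <- mini_vo()
  kg <- build_graph(sim$bundle, onto, reg)

  n_records <- sum(bundle_sizes(sim$bundle))
  expect_length(kg$nodes, n_records + nrow(onto$terms))

  # expected edges by direct counting over the bundle
  n_fk <- 0L; n_inst <- 0L; n_about <- 0L
  for (cn in names(sim$bundle$tables)) {
    tb <- sim$bundle$tables[[cn]]
    cl <- reg$classes[[cn]]
    for (fk in cl$foreign_keys)
      n_fk <- n_fk + sum(!is.na(tb[[fk$column]]))
    for (oc in grep("_ontology_id$", names(tb), value = TRUE))
      n_inst <- n_inst + sum(tb[[oc]] %in% onto$terms$id)
    if (all(c("target_class", "target_id") %in% names(tb)))
      n_about <- n_about + sum(!is.na(tb$target_class) &
                               !is.na(tb$target_id))
  }
  expect_equal(nrow(kg$edges),
               n_fk + n_inst + n_about + nrow(onto$edges))
})

test_that("materials link to their ontology terms and traverse subClassOf*", {
  sim <- simulate_study(sim_config(seed = 52, n_studies = 4,
                                   subjects_per_study = 1, days = c(0, 7)))
  onto <- mini_vo()
  kg <- build_graph(sim$bundle, onto, reg)

  mat <- sim$bundle$tables$Material
  flumist_node <- paste0("Material/",
                         mat$material_id[mat$name == "FluMist"])
  inst <- kg$edges[kg$edges$relation == "instance_of_term", ]
  expect_true(any(inst$source == flumist_node &
                  inst$target == "VO_9100004"))

  under_tiv <- materials_under(kg, "VO_0001236")
  expect_true(flumist_node %in% under_tiv)   # FluMist is under trivalent
  expect_length(under_tiv, 4)
  # instances of the term itself count (zero-hop semantics)
  direct <- materials_under(kg, "VO_9100004")
  expect_identical(direct, flumist_node)
  # the root term collects every material (all are typed as vaccines)
  expect_length(materials_under(kg, "VO_0000001"), 4)
  expect_error(materials_under(kg, "VO_404"), "unknown")
})

test_that("graph traversal equals the relational computation on random inputs", {
  onto <- mini_vo()
  for (seed in c(91, 92, 93, 94, 95)) {
    b <- random_mini_bundle(seed, reg)
    kg <- build_graph(b, onto, reg)
    for (term in c("VO_0001236", "VO_9100005", "VO_9100000")) {
      got <- sort(materials_under(kg, term))
      ids <- descendants(onto, term, include_self = TRUE)
      mat <- b$tables$Material
      oid_cols <- grep("_ontology_id$", names(mat), value = TRUE)
      hit <- rep(FALSE, nrow(mat))
      for (oc in oid_cols) hit <- hit | (mat[[oc]] %in% ids)
      hits <- mat$material_id[hit]
      want <- if (length(hits)) sort(paste0("Material/", hits))
              else character(0)
      expect_identical(got, want)
    }
  }
})

test_that("node details mirror the originating record", {
  b <- empty_bundle(reg)
  b$tables$Subject <- data.frame(subject_id = "Su_1",
                                 stringsAsFactors = FALSE)
  b$tables$Sample <- data.frame(
    sample_id = "Sam_2731", subject_id = "Su_1", type = "expsample",
    expsample_type = "PBMC", collection = "blood draw",
    expsample_reference_name = "GSM733896", stringsAsFactors = FALSE)
  b$tables <- lapply(stats::setNames(names(b$tables), names(b$tables)),
    function(cn) seacdm:::conform_class_table(reg$classes[[cn]],
                                              b$tables[[cn]])$table)
  kg <- build_graph(b, empty_graphs(), reg)
  nd <- node_detail(kg, "Sample/Sam_2731")
  expect_equal(nd$label, "Sample")
  expect_equal(nd$properties$expsample_type, "PBMC")
  expect_equal(nd$properties$collection, "blood draw")
  expect_equal(nd$properties$expsample_reference_name, "GSM733896")
  # properties equal the record's non-empty fields, field by field
  rec <- b$tables$Sample[1, ]
  for (f in names(rec)[!is.na(unlist(rec))])
    expect_equal(nd$properties[[f]], rec[[f]])
  nd2 <- node_detail(kg, "Subject/Su_1")
  expect_setequal(names(nd2$properties), "subject_id")
  expect_error(node_detail(kg, "Sample/NOPE"), "unknown node")
})

test_that("table export round-trips to an isomorphic graph", {
  sim <- simulate_study(sim_config(seed = 53, n_studies = 1,
                                   subjects_per_study = 2, days = c(0, 7)))
  onto <- mini_vo()
  kg <- build_graph(sim$bundle, onto, reg)
  td <- withr::local_tempdir()
  paths <- export_graph(kg, "node_edge_tables", td)
  nodes <- utils::read.csv(paths[1], check.names = FALSE,
                           colClasses = "character")
  edges <- utils::read.csv(paths[2], check.names = FALSE,
                           colClasses = "character")
  expect_equal(nrow(nodes), length(kg$nodes))
  expect_equal(nrow(edges), nrow(kg$edges))
  expect_true(all(c(":ID", ":LABEL") %in% names(nodes)))
  expect_true(all(c(":START_ID", ":END_ID", ":TYPE") %in% names(edges)))

  # naive re-parse reconstructs the same nodes, labels, and edge relation
  # multiset
  expect_setequal(nodes$`:ID`, names(kg$nodes))
  relabel <- vapply(kg$nodes, `[[`, "", "label")
  expect_identical(
    stats::setNames(nodes$`:LABEL`, nodes$`:ID`)[names(kg$nodes)],
    relabel)
  expect_identical(
    sort(paste(edges$`:START_ID`, edges$`:TYPE`, edges$`:END_ID`)),
    sort(paste(kg$edges$source, kg$edges$relation, kg$edges$target)))

  # empty graph exports header-only files
  g0 <- build_graph(empty_bundle(reg), empty_graphs(), reg)
  td0 <- withr::local_tempdir()
  p0 <- export_graph(g0, "node_edge_tables", td0)
  expect_equal(nrow(utils::read.csv(p0[2], check.names = FALSE)), 0)
})

test_that("cypher export writes one MERGE per node and per edge", {
  sim <- simulate_study(sim_config(seed = 54, n_studies = 1,
                                   subjects_per_study = 1, days = c(0, 7)))
  kg <- build_graph(sim$bundle, mini_vo(), reg)
  td <- withr::local_tempdir()
  path <- export_graph(kg, "cypher_script", td)
  lines <- readLines(path)
  expect_length(lines, length(kg$nodes) + nrow(kg$edges))
  expect_equal(sum(grepl("^MERGE \\(n:", lines)), length(kg$nodes))
  expect_equal(sum(grepl("^MATCH .*MERGE \\(a\\)-", lines)),
               nrow(kg$edges))
})
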