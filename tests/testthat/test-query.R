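reg <- build_default_registry()

# one store shared across selection tests
make_sim_store <- function(cfg) {
  sim <- simulate_study(cfg)
  st <- init_store(reg)
  load_bundle(st, sim$bundle)
  list(sim = sim, store = st)
}

test_that("pair selection requires both baseline and follow-up samples", {
  b <- empty_bundle(reg)
  b$tables$Study <- data.frame(study_id = "ST1", stringsAsFactors = FALSE)
  b$tables$Experiment <- data.frame(experiment_id = "E1", study_id = "ST1",
                                    stringsAsFactors = FALSE)
  b$tables$Subject <- data.frame(subject_id = c("S1", "S2"),
                                 experiment_id = "E1", species = "Homo sapiens",
                                 stringsAsFactors = FALSE)
  b$tables$Intervention <- data.frame(
    intervention_id = c("I1", "I2"), subject_id = c("S1", "S2"),
    material = "Fluarix", stringsAsFactors = FALSE)
  # S1 has day 0 and 7; S2 has day 7 only
  b$tables$Sample <- data.frame(
    sample_id = c("SA1", "SA2", "SA3"),
    subject_id = c("S1", "S1", "S2"),
    type = "expsample", collection_time = c(0, 7, 7),
    expsample_reference_name = c("R1", "R2", "R3"),
    stringsAsFactors = FALSE)
  b$tables <- lapply(stats::setNames(names(b$tables), names(b$tables)),
    function(cn) seacdm:::conform_class_table(reg$classes[[cn]],
                                              b$tables[[cn]])$table)
  st <- init_store(reg)
  on.exit(close_store(st))
  load_bundle(st, b)
  pairs <- select_pairs(st, sample_query("Fluarix", day = 7))
  expect_equal(pairs$subject_id, "S1")
  expect_equal(pairs$baseline_ref, "R1")
  expect_equal(pairs$followup_ref, "R2")
  # no match at all is an empty frame, not an error
  expect_equal(nrow(select_pairs(st, sample_query("BCG", day = 7))), 0)
})

test_that("duplicate samples at one day resolve to the first reference with a warning", {
  b <- empty_bundle(reg)
  b$tables$Subject <- data.frame(subject_id = "S1", stringsAsFactors = FALSE)
  b$tables$Intervention <- data.frame(intervention_id = "I1",
                                      subject_id = "S1",
                                      material = "Fluarix",
                                      stringsAsFactors = FALSE)
  b$tables$Sample <- data.frame(
    sample_id = c("SA1", "SA2", "SA3"), subject_id = "S1",
    type = "expsample", collection_time = c(0, 7, 7),
    expsample_reference_name = c("R0", "RZ", "RA"),
    stringsAsFactors = FALSE)
  b$tables <- lapply(stats::setNames(names(b$tables), names(b$tables)),
    function(cn) seacdm:::conform_class_table(reg$classes[[cn]],
                                              b$tables[[cn]])$table)
  st <- init_store(reg)
  on.exit(close_store(st))
  load_bundle(st, b)
  expect_warning(pairs <- select_pairs(st, sample_query("Fluarix", day = 7)),
                 "2 samples at day 7")
  expect_equal(pairs$followup_ref, "RA")   # lexicographically first
})

test_that("ontology-term selection equals the union of per-vaccine queries", {
  ms <- make_sim_store(sim_config(seed = 83, n_studies = 4,
                                  subjects_per_study = 3, days = c(0, 7)))
  on.exit(close_store(ms$store))
  g <- mini_vo()
  by_term <- select_pairs(ms$store, sample_query("VO_0001236", day = 7), g)
  per_vaccine <- do.call(rbind, lapply(
    c("Fluarix", "Fluvirin", "Fluzone", "FluMist"),
    function(v) select_pairs(ms$store, sample_query(v, day = 7))))
  per_vaccine <- per_vaccine[order(per_vaccine$subject_id), , drop = FALSE]
  rownames(per_vaccine) <- NULL
  expect_identical(by_term, per_vaccine)
  expect_equal(nrow(by_term), 12)   # every subject, all four vaccines
  # sex filter restricts to the female half
  fem <- select_pairs(ms$store,
                      sample_query("VO_0001236", day = 7, sex = "female"), g)
  n_female <- sum(ms$sim$bundle$tables$Subject$sex == "female")
  expect_equal(nrow(fem), n_female)
})

test_that("inclusive thresholds: boundary cases pass and floor failures reject", {
  refs <- c(sprintf("B%d", 1:3), sprintf("F%d", 1:3))
  mk <- function(xb, xf) {
    vals <- rbind(boundary = c(rep(xb, 3), rep(xf, 3)))
    colnames(vals) <- refs
    expression_matrix(vals)
  }
  pairs <- data.frame(subject_id = sprintf("S%d", 1:3),
                      baseline_ref = sprintf("B%d", 1:3),
                      followup_ref = sprintf("F%d", 1:3),
                      stringsAsFactors = FALSE)
  # delta exactly 1.0 and follow-up exactly at the 0.2 floor, 3 subjects
  res <- stimulated_genes(mk(-0.8, 0.2), pairs)
  expect_identical(res$stimulated, "boundary")
  # large fold change but both days under the floor
  res2 <- stimulated_genes(mk(0.05, 0.1 + 2), pairs,
                           gene_filter_criteria(min_log2_fc = 1,
                                                expr_floor_log2 = 3))
  expect_identical(res2$stimulated, character())
  # only 2 of 3 subjects passing stays below the subject minimum
  m3 <- mk(-0.8, 0.2)
  m3$values["boundary", "F3"] <- -0.5
  res3 <- stimulated_genes(expression_matrix(m3$values), pairs)
  expect_identical(res3$stimulated, character())
  expect_equal(res3$table$n_passing, 2L)
})

test_that("stimulated set equals the exhaustive oracle on random matrices", {
  for (seed in 1:25) {
    rm <- random_matrix(seed)
    res <- stimulated_genes(rm$matrix, rm$pairs)
    want <- oracle_stimulated(rm$matrix$values, rm$matrix$batch_flag,
                              rm$pairs)
    expect_setequal(res$stimulated, want)
  }
})

test_that("batch-flagged pairs are removed before filtering", {
  rm <- random_matrix(99)
  res_excl <- stimulated_genes(rm$matrix, rm$pairs)
  res_keep <- stimulated_genes(rm$matrix, rm$pairs,
                               gene_filter_criteria(exclude_batch = FALSE))
  flagged <- rm$pairs$subject_id[
    rm$matrix$batch_flag[rm$pairs$baseline_ref] |
    rm$matrix$batch_flag[rm$pairs$followup_ref]]
  expect_gt(length(flagged), 0)
  expect_false(any(flagged %in% colnames(res_excl$pass)))
  expect_true(all(flagged %in% colnames(res_keep$pass)))
})

test_that("tightening criteria is monotone; relaxing recovers all rising genes", {
  rm <- random_matrix(7)
  base <- stimulated_genes(rm$matrix, rm$pairs)$stimulated
  for (crit in list(gene_filter_criteria(min_log2_fc = 1.5),
                    gene_filter_criteria(expr_floor_log2 = 1),
                    gene_filter_criteria(min_subjects = 5))) {
    expect_true(all(stimulated_genes(rm$matrix, rm$pairs,
                                     crit)$stimulated %in% base))
  }
  relaxed <- stimulated_genes(rm$matrix, rm$pairs,
    gene_filter_criteria(min_log2_fc = 1e-300, expr_floor_log2 = -Inf,
                         min_subjects = 1, exclude_batch = FALSE))
  any_rise <- rownames(rm$matrix$values)[apply(
    rm$matrix$values[, rm$pairs$followup_ref] -
    rm$matrix$values[, rm$pairs$baseline_ref], 1,
    function(d) any(d > 0))]
  expect_setequal(relaxed$stimulated, any_rise)
})

test_that("missing sample references are reported by name", {
  rm <- random_matrix(3)
  bad <- rm$pairs
  bad$followup_ref[1] <- "GSM_MISSING"
  expect_error(stimulated_genes(rm$matrix, bad), "GSM_MISSING")
})

test_that("vaccine-class grouping unions descendants' gene lists", {
  g <- mini_vo()
  lists <- list(Fluarix = c("g1", "g2"), Fluzone = c("g2", "g3"),
                Fluvirin = c("g4"), FluMist = c("g5"))
  out <- group_by_vaccine_class(lists, g,
                                c(TIV = "VO_9100006", LAIV = "VO_9100005"))
  expect_setequal(out$TIV, c("g1", "g2", "g3", "g4"))
  expect_setequal(out$LAIV, "g5")
  expect_length(attr(out, "unassigned"), 0)

  # overlapping classes may share genes; unknown vaccines are reported
  expect_warning(
    group_by_vaccine_class(c(lists, list(Shingrix = "g9")), g,
                           c(TIV = "VO_9100006", flu = "VO_9100000")),
    "Shingrix")
  out2 <- suppressWarnings(
    group_by_vaccine_class(c(lists, list(Shingrix = "g9")), g,
                           c(TIV = "VO_9100006", flu = "VO_9100000")))
  expect_true(all(out2$TIV %in% out2$flu))
  expect_identical(attr(out2, "unassigned"), "Shingrix")

  single <- group_by_vaccine_class(lists["FluMist"], g,
                                   c(LAIV = "VO_9100005"))
  expect_identical(single$LAIV, sort(lists$FluMist))
})

test_that("overlap regions partition the union", {
  expect_identical(overlap_counts(list(A = c("x", "y"), B = c("x", "y"))),
                   c(A = 0L, B = 0L, `A&B` = 2L))
  expect_identical(overlap_counts(list(A = "x", B = "y")),
                   c(A = 1L, B = 1L, `A&B` = 0L))
  for (seed in c(31, 32)) {
    sets <- withr::with_seed(seed, lapply(stats::setNames(1:4, LETTERS[1:4]),
      function(i) sample(sprintf("g%02d", 1:30), sample(5:20, 1))))
    counts <- overlap_counts(sets)
    expect_length(counts, 2^4 - 1)
    expect_equal(sum(counts), length(unique(unlist(sets))))
    # brute-force: count each element's membership signature
    brute <- table(vapply(unique(unlist(sets)), function(e)
      paste(names(sets)[vapply(sets, function(s) e %in% s, TRUE)],
            collapse = "&"), ""))
    expect_identical(counts[names(brute)], unlist(as.list(brute))[names(brute)])
  }
})

test_that("gene-list exports round-trip and validate", {
  rm <- random_matrix(12)
  res <- stimulated_genes(rm$matrix, rm$pairs,
                          gene_filter_criteria(min_subjects = 2))
  csv <- tempfile(fileext = ".csv")
  export_results(res, "csv", csv)
  back <- read_results(csv)
  want <- res$table[res$table$stimulated,
                    c("gene", "n_passing", "mean_delta")]
  rownames(want) <- NULL
  expect_equal(back, want)

  js <- tempfile(fileext = ".json")
  export_results(res, "json", js)
  expect_true(validate_results_json(js))
  expect_equal(read_results(js)$gene, want$gene)

  # empty result: header-only CSV, still valid JSON
  none <- stimulated_genes(rm$matrix, rm$pairs,
                           gene_filter_criteria(min_log2_fc = 50))
  csv0 <- tempfile(fileext = ".csv")
  export_results(none, "csv", csv0)
  expect_equal(nrow(read_results(csv0)), 0)
  js0 <- tempfile(fileext = ".json")
  export_results(none, "json", js0)
  expect_true(validate_results_json(js0))
})

test_that("query and criteria constructors reject invalid arguments", {
  expect_error(sample_query("x", day = 7, baseline_day = 7), "baseline_day")
  expect_error(sample_query("x", day = -1), "day")
  expect_error(sample_query("x", day = 7, sex = "other"), "sex")
  expect_error(gene_filter_criteria(min_log2_fc = 0), "min_log2_fc")
  expect_error(gene_filter_criteria(min_subjects = 0), "min_subjects")
})
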