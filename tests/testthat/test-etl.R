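reg <- build_default_registry()

test_that("VIGET connector builds a complete, valid bundle", {
  td <- withr::local_tempdir()
  cfg <- sim_config(n_studies = 3, subjects_per_study = 4, days = c(0, 7),
                    seed = 71)
  simulate_viget_files(cfg, td)
  v <- viget_to_bundle(file.path(td, "metadata.csv"),
                       file.path(td, "expression.csv"))
  expect_equal(nrow(v$bundle$tables$Study), 3)
  expect_equal(nrow(v$bundle$tables$Subject), 12)
  expect_equal(nrow(v$bundle$tables$Sample), 3 * 4 * 2)
  expect_true(validate_bundle(reg, v$bundle)$ok)
  expect_true(all(startsWith(v$bundle$tables$Study$study_id, "VIGET:")))
  # Documentation records the expression file location
  expect_match(v$bundle$tables$Documentation$path, "expression.csv")
  # batch flags carried into the matrix
  sim <- simulate_study(cfg)
  expect_setequal(names(which(v$matrix$batch_flag)),
                  sim$truth$batch_samples)
})

test_that("VIGET connector warns on metadata/matrix mismatches and empty input", {
  td <- withr::local_tempdir()
  simulate_viget_files(sim_config(n_studies = 1, subjects_per_study = 2,
                                  days = c(0, 7), seed = 72), td)
  md <- utils::read.csv(file.path(td, "metadata.csv"),
                        stringsAsFactors = FALSE)
  md$geo_accession[1] <- "GSM_NOT_IN_MATRIX"
  utils::write.csv(md, file.path(td, "metadata.csv"), row.names = FALSE)
  expect_warning(
    expect_warning(
      viget_to_bundle(file.path(td, "metadata.csv"),
                      file.path(td, "expression.csv")),
      "absent from the expression matrix"),
    "absent from the metadata")

  utils::write.csv(md[0, ], file.path(td, "metadata.csv"),
                   row.names = FALSE)
  expect_warning(
    v0 <- viget_to_bundle(file.path(td, "metadata.csv"),
                          file.path(td, "expression.csv")),
    "empty")
  expect_true(all(bundle_sizes(v0$bundle) == 0))
})

test_that("ImmPort merge rules: intervention and sample tables concatenate", {
  td <- withr::local_tempdir()
  mk <- function(name, n, off) {
    utils::write.csv(data.frame(
      intervention_accession = sprintf("IV%02d", off + seq_len(n)),
      subject_accession = "SUB1",
      name_reported = "Fluzone", type_reported = "vaccination"),
      file.path(td, paste0(name, ".csv")), row.names = FALSE)
  }
  mk("intervention", 2, 0); mk("immune_exposure", 3, 10)
  mk("treatment", 4, 20)
  utils::write.csv(data.frame(subject_accession = "SUB1",
                              gender = "female"),
                   file.path(td, "subject.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample_accession = "EX1",
                              subject_accession = "SUB1",
                              expsample_accession = "GSM1"),
                   file.path(td, "expsample.csv"), row.names = FALSE)
  b <- immport_to_bundle(td)
  expect_equal(nrow(b$tables$Intervention), 9)    # 2 + 3 + 4
  expect_equal(b$tables$Sample$type, "expsample")
  src <- b$extended[b$extended$name == "source_table" &
                    b$extended$class == "Intervention", ]
  expect_setequal(unique(src$value),
                  c("intervention", "immune_exposure", "treatment"))
})

test_that("ImmPort assay tables split into Assay plus per-record Results", {
  td <- withr::local_tempdir()
  utils::write.csv(data.frame(subject_accession = "SUB1"),
                   file.path(td, "subject.csv"), row.names = FALSE)
  utils::write.csv(data.frame(
    result_accession = sprintf("R%d", 1:5),
    assay_accession = "A1",
    expsample_accession = NA,
    datatype = "OD", filetype = "csv"),
    file.path(td, "assay_elisa.csv"), row.names = FALSE)
  b <- immport_to_bundle(td)
  expect_equal(nrow(b$tables$Result), 5)
  expect_equal(unique(b$tables$Result$original_assay_type), "elisa")
  expect_equal(nrow(b$tables$Assay), 1)
  expect_equal(b$tables$Assay$assay_type, "elisa")
  expect_true(all(b$tables$Result$assay_id == b$tables$Assay$assay_id))
})

test_that("ImmPort key collisions across merged tables are fatal and named", {
  td <- withr::local_tempdir()
  for (tn in c("intervention", "treatment"))
    utils::write.csv(data.frame(intervention_accession = "IV1",
                                subject_accession = "S1",
                                name_reported = "saline"),
                     file.path(td, paste0(tn, ".csv")), row.names = FALSE)
  utils::write.csv(data.frame(subject_accession = "S1"),
                   file.path(td, "subject.csv"), row.names = FALSE)
  expect_error(immport_to_bundle(td), "key collision.*treatment")
})

test_that("ImmPort emulation round-trips with row conservation", {
  td <- withr::local_tempdir()
  cfg <- sim_config(n_studies = 2, subjects_per_study = 3, days = c(0, 7),
                    seed = 75)
  simulate_immport_tables(cfg, td)
  sim <- simulate_study(cfg)
  b <- immport_to_bundle(td)
  for (cn in c("Study", "Experiment", "Subject", "Intervention", "Sample",
               "Assay", "Result"))
    expect_equal(nrow(b$tables[[cn]]), nrow(sim$bundle$tables[[cn]]),
                 info = cn)
  expect_true(validate_bundle(reg, b)$ok)
  # consolidated keys equal the generator's, modulo the connector prefix
  expect_setequal(sub("^IMMPORT:", "", b$tables$Sample$sample_id),
                  sim$bundle$tables$Sample$sample_id)

  # zero subjects -> header-only files, empty consolidation
  td0 <- withr::local_tempdir()
  simulate_immport_tables(sim_config(n_studies = 1, subjects_per_study = 0,
                                     seed = 76), td0)
  expect_true(file.exists(file.path(td0, "intervention.csv")))
  b0 <- immport_to_bundle(td0)
  expect_true(is.null(b0$tables$Intervention) ||
                nrow(b0$tables$Intervention) == 0)
})

test_that("CELLxGENE connector maps the 10 common variables to fixed targets", {
  cmap <- get_cellxgene_common_map()
  expect_length(cmap, 10)
  expect_setequal(names(cmap),
                  c("organism", "species", "developmental_stage", "disease",
                    "sex", "tissue", "cell_type", "suspension", "assay",
                    "tissue_type"))

  obs <- simulate_cellxgene_obs(sim_config(n_studies = 1,
                                           subjects_per_study = 3,
                                           days = c(0, 7), seed = 77))
  expect_equal(ncol(obs), 22)   # 10 vars + 10 ontology ids + 2 metadata
  b <- cellxgene_to_bundle(obs)
  expect_true(validate_bundle(reg, b)$ok)
  expect_equal(nrow(b$extended), 0)
  expect_equal(nrow(b$tables$Result), nrow(obs))
  expect_equal(nrow(b$tables$Sample), length(unique(obs$sample_id)))
  # paired ontology ids land in the paired columns
  expect_equal(unique(b$tables$Subject$sex_ontology_id[
    b$tables$Subject$sex == "female"]), "PATO_0000383")
  expect_equal(unique(b$tables$Occurrence$disease), "influenza")
})

test_that("CELLxGENE author variables are routed to extended attributes", {
  obs <- simulate_cellxgene_obs(sim_config(n_studies = 1,
                                           subjects_per_study = 2,
                                           days = c(0, 7), extra_vars = 7,
                                           seed = 78))
  b <- cellxgene_to_bundle(obs)
  expect_equal(nrow(b$extended), 7 * nrow(obs))
  expect_setequal(unique(b$extended$class), "Result")

  # a missing common variable warns and yields NA, not failure
  obs2 <- obs[, setdiff(names(obs),
                        c("tissue", "tissue_ontology_term_id"))]
  expect_warning(b2 <- cellxgene_to_bundle(obs2), "tissue")
  expect_true(all(is.na(b2$tables$Sample$tissue)))

  expect_error(cellxgene_to_bundle(obs[, setdiff(names(obs), "sample_id")]),
               "sample_id")
})

test_that("CELLxGENE H5ad path reads the obs frame written by anndata", {
  skip_if_not_installed("rhdf5")
  td <- withr::local_tempdir()
  obs_csv <- file.path(td, "obs.csv")
  obs <- simulate_cellxgene_obs(sim_config(n_studies = 1,
                                           subjects_per_study = 2,
                                           days = c(0, 7), seed = 79),
                                path = obs_csv)
  h5 <- file.path(td, "mini.h5ad")
  script <- sprintf(paste0(
    "import pandas as pd, numpy as np, anndata as ad\n",
    "obs = pd.read_csv(%s, dtype=str, keep_default_na=False)\n",
    "obs.index = obs['observation_join_id']\n",
    "a = ad.AnnData(X=np.zeros((len(obs), 2)), obs=obs)\n",
    "a.write_h5ad(%s)\n"), deparse(obs_csv), deparse(h5))
  status <- system2("python", c("-c", shQuote(script)))
  expect_identical(status, 0L)
  if (status != 0L) return()   # do not read a partially written file
  got <- read_h5ad_obs(h5)
  expect_true(all(names(obs) %in% names(got)))
  expect_identical(got$sample_id, obs$sample_id)
  b <- cellxgene_to_bundle(h5)
  expect_true(validate_bundle(reg, b)$ok)
  expect_equal(nrow(b$tables$Result), nrow(obs))
})

test_that("bundles from all connectors merge into one store", {
  td <- withr::local_tempdir()
  cfg <- sim_config(n_studies = 1, subjects_per_study = 2, days = c(0, 7),
                    seed = 80)
  simulate_viget_files(cfg, td)
  v <- viget_to_bundle(file.path(td, "metadata.csv"),
                       file.path(td, "expression.csv"))
  td2 <- withr::local_tempdir()
  simulate_immport_tables(cfg, td2)
  im <- immport_to_bundle(td2)
  cx <- cellxgene_to_bundle(simulate_cellxgene_obs(cfg))
  m <- merge_bundles(v$bundle, im, cx, registry = reg)
  expect_true(validate_bundle(reg, m)$ok)
  st <- init_store(reg)
  on.exit(close_store(st))
  rep <- load_bundle(st, m)
  expect_equal(sum(rep), sum(bundle_sizes(m)) + nrow(m$extended))
})
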