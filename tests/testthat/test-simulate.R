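test_that("configuration errors name the offending field", {
  expect_error(sim_config(frac_differential = 1.5), "frac_differential")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(zero_inflation = 1), "zero_inflation")
  expect_error(sim_config(n_per_group = 1), "n_per_group")
  expect_error(sim_config(library_reads = c(1e6, 0)), "library_reads")
  expect_error(sim_config(n_contaminants = -1), "n_contaminants")
})

test_that("truth labels match the configuration and align with the table", {
  cfg <- sim_config(n_annotations = 400, frac_differential = 0.1,
                    n_contaminants = 30, seed = 5)
  sim <- simulate_counts(cfg)
  expect_equal(nrow(sim$counts), 430)
  expect_identical(sim$counts$annotation_id, sim$truth$annotation_id)
  expect_equal(sum(sim$truth$label == "differential"), 40)
  expect_equal(sum(sim$truth$label == "contaminant"), 30)
  expect_true(all(sim$truth$log2fc[sim$truth$label != "differential"] == 0))
  expect_true(all(abs(sim$truth$log2fc[sim$truth$label == "differential"]) == 2))

  # no-signal case
  sim0 <- simulate_counts(sim_config(n_annotations = 100,
                                     frac_differential = 0, seed = 1))
  expect_equal(sum(sim0$truth$label == "differential"), 0)
})

test_that("every contaminant is observable in a control column", {
  sim <- simulate_counts(sim_config(n_annotations = 200, n_contaminants = 50,
                                    seed = 8))
  m <- as.matrix(sim$counts[, -1])
  rownames(m) <- sim$counts$annotation_id
  ctl <- sim$metadata$sample_id[sim$metadata$class %in% c("mock", "soil")]
  cont <- sim$truth$annotation_id[sim$truth$label == "contaminant"]
  expect_true(all(rowSums(m[cont, ctl, drop = FALSE] > 0) > 0))
  # non-contaminants never appear in controls
  other <- setdiff(rownames(m), cont)
  expect_true(all(m[other, ctl] == 0))
})

test_that("identical seeds give byte-identical fixture files", {
  cfg <- sim_config(n_annotations = 150, n_contaminants = 10, seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture_set(d1, cfg)
  m2 <- write_fixture_set(d2, cfg)
  for (i in seq_len(nrow(m1))) {
    expect_identical(readLines(m1$path[i]), readLines(m2$path[i]))
  }
})

test_that("fixture set round-trips through the readers", {
  cfg <- sim_config(n_annotations = 120, n_contaminants = 15, seed = 3)
  dir <- withr::local_tempdir()
  manifest <- write_fixture_set(dir, cfg)
  expect_setequal(manifest$role, c("counts", "metadata", "go_mapping", "truth"))
  got <- read_count_table(manifest$path[manifest$role == "counts"],
                          manifest$path[manifest$role == "metadata"])
  expect_equal(nrow(got$counts), 135)
  expect_equal(nrow(got$metadata), 8)  # 6 experimental + mock + soil
  truth <- read_truth(manifest$path[manifest$role == "truth"])
  expect_equal(nrow(truth), nrow(got$counts))
  mapping <- read_go_mapping(manifest$path[manifest$role == "go_mapping"])
  # many-to-many with gaps: some ID maps to 2+ terms, some to none
  per_id <- table(mapping$uniprot_id)
  expect_true(any(per_id >= 2))
  expect_true(length(setdiff(truth$annotation_id, mapping$uniprot_id)) >= 1)
})

test_that("dispersion near zero recovers Poisson mean-variance at n = 1000 draws", {
  cfg <- sim_config(n_annotations = 100, n_per_group = 500,
                    library_reads = 1e6, frac_differential = 0,
                    dispersion = 1e-8, zero_inflation = 0,
                    n_contaminants = 0, n_mock = 0, n_soil = 0,
                    baseline_meanlog = log(50), baseline_sdlog = 1, seed = 9)
  sim <- simulate_counts(cfg)
  m <- as.matrix(sim$counts[, -1])
  ratio <- apply(m, 1, var) / rowMeans(m)
  expect_gt(mean(ratio), 0.98)
  expect_lt(mean(ratio), 1.02)
  expect_true(all(ratio > 0.8 & ratio < 1.2))
})

test_that("null annotation means are treatment-independent", {
  cfg <- sim_config(n_annotations = 1000, frac_differential = 0,
                    library_reads = 1e6, n_contaminants = 0,
                    n_mock = 0, n_soil = 0, seed = 13)
  sim <- simulate_counts(cfg)
  m <- as.matrix(sim$counts[, -1])
  trt <- treatment_of(sim$counts, sim$metadata)
  mw <- rowMeans(m[, trt == "watered"])
  md <- rowMeans(m[, trt == "drought"])
  expect_gt(t.test(mw, md, paired = TRUE)$p.value, 0.001)
})

test_that("empirical zero fraction is at least the configured zero inflation", {
  sim <- simulate_counts(sim_config(n_annotations = 1000,
                                    zero_inflation = 0.25,
                                    n_contaminants = 0, n_mock = 0,
                                    n_soil = 0, seed = 4))
  m <- as.matrix(sim$counts[, -1])
  expect_gte(mean(m == 0), 0.25)
})

test_that("doubling a library size doubles that column's total", {
  base_reads <- rep(1e6, 6)
  mk <- function(reads, s) simulate_counts(sim_config(
    n_annotations = 5000, library_reads = reads, frac_differential = 0,
    dispersion = 0.05, zero_inflation = 0, n_contaminants = 0,
    n_mock = 0, n_soil = 0, baseline_sdlog = 0.5, seed = s))
  a <- mk(base_reads, 6)
  b <- mk(c(2e6, base_reads[-1]), 6)
  ratio <- sum(b$counts[[2]]) / sum(a$counts[[2]])
  expect_gt(ratio, 2 * 0.95)
  expect_lt(ratio, 2 * 1.05)
})

test_that("trait generator validates inputs and recovers a null effect", {
  expect_error(simulate_traits(1, 0.1, 0.05), "n_per_group")
  expect_error(simulate_traits(10, 0.1, 0), "sd")
  tf <- fit_trait(simulate_traits(200, 0, 0.05, seed = 2))
  expect_lt(abs(tf$estimate), 3 * tf$se)
})
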