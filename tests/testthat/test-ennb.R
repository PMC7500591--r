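test_that("a maximal penalty selects nothing on pure noise", {
  sim <- simulate_counts(null_config(31, n_annotations = 300))
  sel <- elastic_net_select(sim$counts,
                            treatment_of(sim$counts, sim$metadata),
                            lambda = 1e9)
  expect_length(sel$selected, 0)
})

test_that("selection needs 3 replicates per group and points at imputation", {
  counts <- tiny_counts(matrix(rpois(40, 50), ncol = 4))
  expect_error(
    elastic_net_select(counts, c("watered", "watered", "drought", "drought")),
    "impute"
  )
})

test_that("duplicated annotations are selected together (grouping effect)", {
  base <- withr::with_seed(5, matrix(rnbinom(600, mu = 100, size = 5),
                                     ncol = 6))
  sig <- c(10, 12, 11, 80, 90, 85)
  counts <- tiny_counts(rbind(base, sig, sig),
                        ids = c(paste0("g", 1:100), "dupA", "dupB"))
  trt <- rep(c("watered", "drought"), each = 3)
  sel <- elastic_net_select(counts, trt, seed = 1)
  expect_equal("dupA" %in% sel$selected, "dupB" %in% sel$selected)
  co <- sel$coefficients
  if (all(c("dupA", "dupB") %in% co$annotation_id)) {
    ca <- co$coefficient[co$annotation_id == "dupA"]
    cb <- co$coefficient[co$annotation_id == "dupB"]
    expect_lt(abs(ca - cb) / max(abs(ca), abs(cb)), 0.05)
  }
})

test_that("identical groups give a zero coefficient and p = 1", {
  counts <- tiny_counts(matrix(7, nrow = 2, ncol = 6))
  res <- nb_test(counts, rep(c("watered", "drought"), each = 3))
  expect_equal(res$estimate, c(0, 0), tolerance = 1e-8)
  expect_equal(res$p_value, c(1, 1), tolerance = 1e-6)
})

test_that("the NB coefficient is drought relative to watered", {
  counts <- tiny_counts(matrix(c(50, 52, 48, 201, 198, 205), nrow = 1))
  res <- nb_test(counts, rep(c("watered", "drought"), each = 3),
                 dispersion = 0.01)
  expect_gt(res$estimate, 0)          # higher under drought
  expect_equal(res$log2_fc, 2, tolerance = 0.2)
})

test_that("a planted 4-fold change at high counts is recovered within 3 SE", {
  hits <- 0; tot <- 0
  for (s in 1:3) {
    cfg <- sim_config(n_annotations = 400, frac_differential = 0.05,
                      log2_fold_changes = 2, baseline_meanlog = log(2000),
                      baseline_sdlog = 0.5, zero_inflation = 0,
                      n_contaminants = 0, n_mock = 0, n_soil = 0,
                      seed = 100 + s)
    sim <- simulate_counts(cfg)
    res <- suppressWarnings(nb_test(sim$counts,
                                    treatment_of(sim$counts, sim$metadata),
                                    offsets = tmm_offsets(sim$counts)))
    j <- dplyr::inner_join(res, sim$truth, by = "annotation_id")
    d <- j[j$label == "differential", ]
    hits <- hits + sum(abs(d$estimate - d$log2fc * log(2)) < 3 * d$se)
    tot <- tot + nrow(d)
  }
  expect_gte(hits / tot, 0.95)
})

test_that("null p-values are approximately uniform", {
  sim <- simulate_counts(null_config(77))
  m <- sim$counts
  keep <- rowSums(as.matrix(m[, -1])) > 0 &
    apply(as.matrix(m[, -1]), 1, var) > 0
  m <- m[keep, ]
  res <- suppressWarnings(nb_test(m, treatment_of(m, sim$metadata),
                                  offsets = tmm_offsets(m)))
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("the pipeline refuses mixed sites and demands filtered input", {
  sim <- simulate_counts(sim_config(n_annotations = 50, seed = 2))
  md <- sim$metadata
  md$site[1] <- "DE"
  filt <- filter_contaminants(sim$counts, md)
  expect_error(run_ennb(filt$counts, filt$metadata), "per-site")
  expect_error(run_ennb(sim$counts, sim$metadata), "filter_contaminants")
})

test_that("significant calls are contained in the stage-1 selection and monotone in alpha", {
  sim <- simulate_counts(sim_config(n_annotations = 400, n_contaminants = 20,
                                    seed = 14))
  filt <- filter_contaminants(sim$counts, sim$metadata)
  fit <- suppressMessages(run_ennb(filt$counts, filt$metadata,
                                   method = "tmm", alpha = 0.01, seed = 14))
  res <- fit$results
  expect_true(all(res$annotation_id[res$significant] %in%
                    res$annotation_id[res$selected]))
  s001 <- significant_annotations(fit, 0.001)
  s01 <- significant_annotations(fit, 0.01)
  s05 <- significant_annotations(fit, 0.05)
  expect_true(all(s001 %in% s01))
  expect_true(all(s01 %in% s05))
  expect_length(significant_annotations(fit, 0), 0)
})

test_that("the pipeline is deterministic under a fixed seed", {
  sim <- simulate_counts(sim_config(n_annotations = 300, n_contaminants = 10,
                                    seed = 9))
  filt <- filter_contaminants(sim$counts, sim$metadata)
  f1 <- suppressMessages(run_ennb(filt$counts, filt$metadata, seed = 9))
  f2 <- suppressMessages(run_ennb(filt$counts, filt$metadata, seed = 9))
  expect_identical(tidy(f1), tidy(f2))
  expect_equal(glance(f1), glance(f2))
})

test_that("numeric method codes map to tmm and deseq", {
  sim <- simulate_counts(sim_config(n_annotations = 200, n_contaminants = 5,
                                    seed = 4))
  filt <- filter_contaminants(sim$counts, sim$metadata)
  f1 <- suppressMessages(run_ennb(filt$counts, filt$metadata, method = 1, seed = 4))
  f2 <- suppressMessages(run_ennb(filt$counts, filt$metadata, method = "tmm", seed = 4))
  expect_identical(f1$method, "tmm")
  expect_identical(tidy(f1), tidy(f2))
  f3 <- suppressMessages(run_ennb(filt$counts, filt$metadata, method = 2, seed = 4))
  expect_identical(f3$method, "deseq")
})
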