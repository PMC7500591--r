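# literal reimplementation of the TMM definition, independent of the
# package internals: plain loops, quantile-free rank trimming
brute_tmm <- function(m, trim_m = 0.3, trim_a = 0.05) {
  libs <- colSums(m)
  ref <- which.max(libs)
  f <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    if (j == ref) { f[j] <- 1; next }
    M <- c(); A <- c(); w <- c()
    for (i in seq_len(nrow(m))) {
      if (m[i, j] > 0 && m[i, ref] > 0) {
        pj <- m[i, j] / libs[j]
        pr <- m[i, ref] / libs[ref]
        M <- c(M, log2(pj / pr))
        A <- c(A, (log2(pj) + log2(pr)) / 2)
        w <- c(w, 1 / ((libs[j] - m[i, j]) / (libs[j] * m[i, j]) +
                         (libs[ref] - m[i, ref]) / (libs[ref] * m[i, ref])))
      }
    }
    n <- length(M)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    keep <- rank(M) >= lo_m & rank(M) <= hi_m &
      rank(A) >= lo_a & rank(A) <= hi_a
    f[j] <- 2^(sum(M[keep] * w[keep]) / sum(w[keep]))
  }
  f / exp(mean(log(f)))
}

test_that("TMM factors are 1 for identical and depth-scaled columns", {
  m <- withr::with_seed(1, matrix(rpois(20, 100), ncol = 2))
  same <- tiny_counts(cbind(m[, 1], m[, 1]))
  expect_equal(tmm_factors(same)$factor, c(1, 1))
  # a pure depth difference is library size, not composition
  doubled <- tiny_counts(cbind(m[, 1], 2 * m[, 1]))
  expect_equal(tmm_factors(doubled)$factor, c(1, 1))
})

test_that("an abundant annotation deflates its sample's TMM factor", {
  a <- c(100, 150, 80, 120, 90, 110)
  b <- a
  b[1] <- 8 * a[1]
  counts <- tiny_counts(cbind(A = a, B = b))
  f <- tmm_factors(counts)
  expect_lt(f$factor[f$sample_id == "B"], 1)
})

test_that("TMM matches a brute-force reimplementation on a 10-gene table", {
  m <- withr::with_seed(42, cbind(A = rpois(10, 200), B = rpois(10, 400),
                                  C = rpois(10, 100)))
  got <- tmm_factors(tiny_counts(m))$factor
  expect_equal(got, brute_tmm(m), tolerance = 1e-10)
})

test_that("TMM agrees with edgeR's calcNormFactors on a toy table", {
  m <- withr::with_seed(42, cbind(A = rpois(10, 200), B = rpois(10, 400),
                                  C = rpois(10, 100)))
  got <- tmm_factors(tiny_counts(m))$factor
  ref <- which.max(colSums(m))
  oracle <- edgeR::calcNormFactors(m, refColumn = ref)
  expect_equal(got, unname(oracle), tolerance = 1e-8)
})

test_that("normalization factors are invariant to global count rescaling", {
  m <- withr::with_seed(3, matrix(rpois(30, 150), ncol = 3))
  c1 <- tiny_counts(m)
  c10 <- tiny_counts(10 * m)
  expect_equal(tmm_factors(c1)$factor, tmm_factors(c10)$factor,
               tolerance = 1e-12)
  expect_equal(deseq_size_factors(c1)$factor,
               deseq_size_factors(c10)$factor, tolerance = 1e-12)
})

test_that("an all-zero sample is an error naming it", {
  counts <- tiny_counts(cbind(A = c(1, 2), B = c(0, 0)))
  expect_error(tmm_factors(counts), "B")
})

test_that("size factors reflect pure scaling exactly", {
  m <- withr::with_seed(2, matrix(rpois(40, 80) + 1, ncol = 2))
  same <- tiny_counts(cbind(m[, 1], m[, 1]))
  sf <- deseq_size_factors(same)$factor
  expect_equal(sf[1], sf[2])
  tripled <- tiny_counts(cbind(A = m[, 1], B = 3 * m[, 1]))
  sf <- deseq_size_factors(tripled)
  expect_equal(sf$factor[sf$sample_id == "B"] /
                 sf$factor[sf$sample_id == "A"], 3, tolerance = 1e-12)
})

test_that("size factors match the hand-computed 4-gene example", {
  m <- cbind(A = c(10, 20, 40, 100), B = c(20, 40, 80, 200),
             C = c(5, 10, 20, 50))
  # geometric means per gene: exp(mean(log count)); factor_j = median ratio
  gm <- apply(m, 1, function(r) exp(mean(log(r))))
  expected <- apply(m, 2, function(col) median(col / gm))
  got <- deseq_size_factors(tiny_counts(m))
  expect_equal(got$factor, unname(expected), tolerance = 1e-12)
})

test_that("size factors match DESeq2's median-of-ratios on a toy table", {
  m <- withr::with_seed(42, cbind(A = rpois(10, 200), B = rpois(10, 400),
                                  C = rpois(10, 100)))
  got <- deseq_size_factors(tiny_counts(m))$factor
  oracle <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(got, unname(oracle), tolerance = 1e-10)
})

test_that("size-factor fallback handles tables with no all-positive gene", {
  m <- cbind(A = c(10, 0, 30), B = c(0, 20, 15), C = c(12, 18, 0))
  counts <- tiny_counts(m)
  expect_error(deseq_size_factors(counts, fallback = FALSE), "fallback")
  sf <- deseq_size_factors(counts)$factor
  expect_true(all(is.finite(sf) & sf > 0))
})
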