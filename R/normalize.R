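#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes between-sample normalization factors as the weighted trimmed
#' mean of per-annotation log2 ratios against a reference column, the
#' classic TMM definition: annotations zero in either column are
#' excluded, the most extreme `trim_logratio` tails of the log-ratio
#' distribution and `trim_abs` tails of the average-abundance
#' distribution are trimmed (rank-based, two-sided), and the surviving
#' log ratios are averaged with inverse asymptotic-variance (delta
#' method) weights. Factors are rescaled to geometric mean 1. A factor
#' below 1 means the sample's counts are deflated relative to depth
#' (e.g. a few very abundant annotations soak up its reads).
#'
#' @param counts count tibble (`annotation_id` + sample columns).
#' @param trim_logratio two-sided trim proportion on log ratios
#'   (default 0.3).
#' @param trim_abs two-sided trim proportion on average log abundance
#'   (default 0.05).
#' @param ref reference sample ID; default is the highest-depth sample
#'   (largest column total).
#' @return tibble with `sample_id`, `factor` (geometric mean 1),
#'   `lib_size` (column total) and `method = "tmm"`.
#' @export
tmm_factors <- function(counts, trim_logratio = 0.3, trim_abs = 0.05,
                        ref = NULL) {
  validate_counts(counts)
  m <- counts_matrix(counts)
  if (ncol(m) < 2) rlang::abort("TMM needs at least 2 samples")
  libs <- colSums(m)
  all_zero <- colnames(m)[libs == 0]
  if (length(all_zero)) {
    rlang::abort(paste0("sample(s) with all-zero counts: ",
                        paste(all_zero, collapse = ", ")))
  }
  ref <- ref %||% colnames(m)[which.max(libs)]
  if (!ref %in% colnames(m)) rlang::abort(paste0("unknown ref sample: ", ref))
  f <- vapply(colnames(m), function(j) {
    if (j == ref) return(1)
    tmm_pair(m[, j], m[, ref], libs[[j]], libs[[ref]],
             trim_logratio, trim_abs)
  }, numeric(1))
  f <- f / geometric_mean(f)
  tibble::tibble(sample_id = colnames(m), factor = unname(f),
                 lib_size = unname(libs), method = "tmm")
}

# one observed-vs-reference TMM factor; rank-based two-sided trimming
# and inverse binomial-variance weights
tmm_pair <- function(obs, ref, lib_obs, lib_ref, trim_logratio, trim_abs) {
  ok <- obs > 0 & ref > 0
  if (!any(ok)) {
    rlang::warn("no annotation expressed in both sample and reference; factor set to 1")
    return(1)
  }
  obs <- obs[ok]; ref <- ref[ok]
  log_r <- log2((obs / lib_obs) / (ref / lib_ref))
  abs_e <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  v <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  if (max(abs(log_r)) < 1e-6) return(1)
  n <- length(log_r)
  lo_l <- floor(n * trim_logratio) + 1
  hi_l <- n + 1 - lo_l
  lo_s <- floor(n * trim_abs) + 1
  hi_s <- n + 1 - lo_s
  keep <- rank(log_r) >= lo_l & rank(log_r) <= hi_l &
    rank(abs_e) >= lo_s & rank(abs_e) <= hi_s
  w <- 1 / v
  fval <- sum(log_r[keep] * w[keep]) / sum(w[keep])
  if (!is.finite(fval)) fval <- 0
  2^fval
}

#' Median-of-ratios (DESeq-type) size factors
#'
#' Each sample's size factor is the median over annotations of its count
#' divided by the annotation's geometric mean across samples
#' (the pseudo-reference). Only annotations with nonzero counts in every
#' sample enter the reference; if none exist, an all-positive-counts
#' fallback computes per-annotation geometric means over the samples
#' where the annotation is present (set `fallback = FALSE` to error
#' instead). Unlike TMM factors, size factors absorb sequencing depth,
#' so they are used directly as offsets rather than multiplied by
#' library size.
#'
#' @param counts count tibble.
#' @param fallback use the positive-counts fallback when no annotation
#'   is present in all samples (default `TRUE`).
#' @return tibble with `sample_id`, `factor`, `lib_size`,
#'   `method = "deseq"`.
#' @export
deseq_size_factors <- function(counts, fallback = TRUE) {
  validate_counts(counts)
  m <- counts_matrix(counts)
  logm <- log(m)
  log_gm <- rowMeans(logm)
  usable <- is.finite(log_gm)
  if (any(usable)) {
    sf <- apply(logm[usable, , drop = FALSE], 2, function(lc) {
      exp(median(lc - log_gm[usable]))
    })
  } else if (fallback) {
    # positive-count subset: geometric mean over samples where present
    log_gm_pos <- apply(logm, 1, function(r) mean(r[is.finite(r)]))
    ok_rows <- is.finite(log_gm_pos)
    sf <- apply(logm[ok_rows, , drop = FALSE], 2, function(lc) {
      d <- lc - log_gm_pos[ok_rows]
      d <- d[is.finite(d)]
      if (!length(d)) return(NA_real_)
      exp(median(d))
    })
    if (any(!is.finite(sf))) {
      rlang::abort("size-factor fallback failed: a sample shares no annotation with the reference")
    }
  } else {
    rlang::abort("no annotation has nonzero counts in every sample and fallback is disabled")
  }
  tibble::tibble(sample_id = colnames(m), factor = unname(sf),
                 lib_size = unname(colSums(m)), method = "deseq")
}

# per-sample log offsets for the NB stage from a factor tibble:
# TMM factors multiply library size (effective library), DESeq size
# factors already contain depth. Centered so intercepts stay comparable.
norm_offsets <- function(factors) {
  off <- switch(factors$method[1],
    tmm = log(factors$factor * factors$lib_size),
    deseq = log(factors$factor),
    rlang::abort("unknown normalization method")
  )
  setNames(off - mean(off), factors$sample_id)
}
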