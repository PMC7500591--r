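#' Classify sequencing depth into the study's depth classes
#'
#' Depth classes partition the read-count axis: `small` below 233k reads,
#' `moderate` 233-500k, `large` 500k-1.7m, `deep` at and above 1.7m. The
#' published class bounds leave 1.6-1.7m unnamed ("large" up to 1.6m,
#' "deep" above 1.7m); that interval is assigned to `large` here so the
#' classes are a total partition.
#'
#' @param total_reads non-negative read counts (vectorized).
#' @return factor with levels `small < moderate < large < deep`.
#' @export
classify_depth <- function(total_reads) {
  if (any(!is.finite(total_reads)) || any(total_reads < 0)) {
    rlang::abort("`total_reads` must be non-negative and finite")
  }
  cut(total_reads,
      breaks = c(-Inf, 233e3, 500e3, 1.7e6, Inf),
      labels = c("small", "moderate", "large", "deep"),
      right = FALSE, ordered_result = TRUE)
}

#' Remove annotations observed in mock or soil control samples
#'
#' Any annotation with a count above `threshold` (default 0: any
#' presence) in *any* mock or soil sample is treated as a contaminant
#' and removed from all samples; the control columns themselves are then
#' dropped from the returned table. Removal is global across sites.
#'
#' @param counts count tibble (`annotation_id` + sample columns).
#' @param metadata sample metadata with `sample_id` and `class`.
#' @param threshold counts at or below this value in controls do not
#'   trigger removal.
#' @return list with `counts` (cleaned tibble, control columns dropped),
#'   `metadata` (control rows dropped) and `removed_ids` (character).
#' @export
filter_contaminants <- function(counts, metadata, threshold = 0) {
  validate_counts(counts, metadata)
  md <- aligned_metadata(counts, metadata)
  ctl <- md$sample_id[md$class %in% c("mock", "soil")]
  if (!length(ctl)) {
    rlang::warn("no mock or soil samples present; returning table unchanged")
    return(list(counts = counts, metadata = metadata,
                removed_ids = character(0)))
  }
  m <- counts_matrix(counts)
  present <- rowSums(m[, ctl, drop = FALSE] > threshold) > 0
  removed_ids <- rownames(m)[present]
  keep_samples <- setdiff(colnames(m), ctl)
  cleaned <- counts[!present, c(names(counts)[1], keep_samples)]
  list(counts = cleaned,
       metadata = metadata[!metadata$sample_id %in% ctl, , drop = FALSE],
       removed_ids = removed_ids)
}

#' Scale counts to counts-per-megabase
#'
#' Divides each sample column by its megabases-sequenced denominator.
#'
#' @param counts count tibble.
#' @param denominators positive numeric, one per sample column (named by
#'   sample ID, or unnamed in column order).
#' @return count tibble on the counts-per-megabase scale.
#' @export
normalize_cpm <- function(counts, denominators) {
  validate_counts(counts)
  samples <- names(counts)[-1]
  if (!is.null(names(denominators))) {
    miss <- setdiff(samples, names(denominators))
    if (length(miss)) {
      rlang::abort(paste0("no denominator for samples: ",
                          paste(miss, collapse = ", ")))
    }
    denominators <- denominators[samples]
  } else if (length(denominators) != length(samples)) {
    rlang::abort("`denominators` must have one value per sample column")
  }
  if (any(!is.finite(denominators)) || any(denominators <= 0)) {
    rlang::abort("denominators must be strictly positive")
  }
  m <- sweep(counts_matrix(counts), 2, denominators, "/")
  out <- matrix_counts(m)
  names(out)[1] <- names(counts)[1]
  out
}

#' Impute a third replicate for a two-sample treatment group
#'
#' The per-annotation negative binomial stage needs three replicates per
#' group; field campaigns sometimes lose one (the study lost one drought
#' sample at its most intensely droughted site). Given the two observed
#' columns of a group, this draws one pseudo-replicate per annotation
#' from a negative binomial whose mean is the average of the two
#' observed counts and whose dispersion is a per-annotation
#' method-of-moments estimate floored at `dispersion_floor`. The imputed
#' column is appended and flagged `imputed = TRUE` in the metadata so it
#' can be excluded from any summary that must not treat it as data.
#'
#' @param counts count tibble containing the group's two sample columns.
#' @param metadata sample metadata.
#' @param sample_ids exactly two sample IDs forming the group.
#' @param seed integer seed; imputation is deterministic given the seed.
#' @param dispersion_floor lower bound for the method-of-moments
#'   dispersion (default 0.01).
#' @return list with `counts` (one appended column) and `metadata` (one
#'   appended row, `imputed = TRUE`). The observed columns are unchanged.
#' @export
impute_replicate <- function(counts, metadata, sample_ids, seed = 1L,
                             dispersion_floor = 0.01) {
  validate_counts(counts, metadata)
  if (length(sample_ids) != 2) {
    rlang::abort("imputation needs a group of exactly 2 samples: 3+ needs no imputation, 1 is unanalyzable")
  }
  miss <- setdiff(sample_ids, names(counts)[-1])
  if (length(miss)) {
    rlang::abort(paste0("samples not in table: ", paste(miss, collapse = ", ")))
  }
  m <- counts_matrix(counts)[, sample_ids, drop = FALSE]
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  phi <- pmax((v - mu) / mu^2, dispersion_floor)
  phi[!is.finite(phi)] <- dispersion_floor
  new_col <- withr::with_seed(seed, {
    out <- numeric(length(mu))
    pos <- mu > 0
    out[pos] <- rnbinom(sum(pos), mu = mu[pos], size = 1 / phi[pos])
    out
  })
  new_id <- paste0(sample_ids[1], "_imp1")
  counts[[new_id]] <- new_col
  md_row <- metadata[metadata$sample_id == sample_ids[1], , drop = FALSE]
  md_row$sample_id <- new_id
  md_row$imputed <- TRUE
  if (!is.null(md_row$reads)) {
    md_row$reads <- geometric_mean(metadata$reads[metadata$sample_id %in% sample_ids])
  }
  metadata$imputed <- metadata$imputed %||% FALSE
  list(counts = counts, metadata = dplyr::bind_rows(metadata, md_row))
}
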