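# internal helpers shared across modules

# counts tibble -> numeric matrix with annotation_id rownames
counts_matrix <- function(counts) {
  stopifnot(is.data.frame(counts))
  id_col <- names(counts)[1]
  m <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    rlang::abort("count columns must be numeric")
  }
  rownames(m) <- as.character(counts[[id_col]])
  m
}

matrix_counts <- function(m) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(annotation_id = rownames(m)), out)
}

# validate a counts tibble (+ optional metadata) against the container
# invariants: unique ids, finite non-negative counts, metadata coverage
validate_counts <- function(counts, metadata = NULL) {
  if (!is.data.frame(counts) || ncol(counts) < 2) {
    rlang::abort("`counts` must be a data frame: annotation id column + >=1 sample column")
  }
  ids <- counts[[1]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    rlang::abort(paste0("duplicate annotation IDs: ",
                        paste(utils::head(dup, 5), collapse = ", ")))
  }
  m <- counts_matrix(counts)
  if (any(!is.finite(m))) rlang::abort("counts contain non-finite values")
  if (any(m < 0)) rlang::abort("counts contain negative values")
  if (!is.null(metadata)) {
    missing <- setdiff(colnames(m), metadata$sample_id)
    if (length(missing)) {
      rlang::abort(paste0("samples missing from metadata: ",
                          paste(missing, collapse = ", ")))
    }
  }
  invisible(counts)
}

# metadata rows for the sample columns of a counts tibble, in column order
aligned_metadata <- function(counts, metadata) {
  samples <- names(counts)[-1]
  metadata[match(samples, metadata$sample_id), , drop = FALSE]
}

geometric_mean <- function(x) exp(mean(log(x)))

# 0/1 coding of a two-level treatment. "watered" is always the baseline
# so the fitted coefficient reads drought-vs-watered; for any other pair
# of labels the first sorted level is baseline.
treatment_indicator <- function(labels) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) rlang::abort("`treatment` must have exactly 2 levels")
  if (setequal(lev, c("watered", "drought"))) lev <- c("watered", "drought")
  list(g = as.numeric(labels == lev[2]), levels = lev)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integerish = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper &&
    (!integerish || x == round(x))
  if (!ok) {
    rlang::abort(paste0("invalid `", name, "`: must be ",
                        if (integerish) "an integer " else "a number ",
                        if (strict_lower) "> " else ">= ", lower,
                        if (is.finite(upper)) paste0(" and <= ", upper) else ""))
  }
  invisible(x)
}
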