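#' Read an annotation-by-sample count table
#'
#' Reads a tab-separated gene-families table in the HUMAnN2 dialect
#' (first column header `# Gene Family`) or the plain `annotation_id`
#' dialect; both parse identically. All remaining columns are numeric
#' sample columns. Rows whose counts are all zero are retained: any
#' filtering is an explicit, logged step elsewhere.
#'
#' @param path count TSV path.
#' @param metadata_path optional sample metadata CSV
#'   (`sample_id, site, treatment, class`, ...). When supplied, every
#'   sample column must have a metadata row, and the result carries the
#'   metadata.
#' @return list with `counts` (tibble, first column `annotation_id`) and
#'   `metadata` (tibble or `NULL`).
#' @export
read_count_table <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  counts <- readr::read_tsv(path, show_col_types = FALSE, comment = "")
  names(counts)[1] <- "annotation_id"
  counts$annotation_id <- as.character(counts$annotation_id)
  metadata <- NULL
  if (!is.null(metadata_path)) {
    metadata <- read_sample_metadata(metadata_path)
  }
  validate_counts(counts, metadata)
  list(counts = counts, metadata = metadata)
}

#' Read a sample metadata table
#'
#' @param path CSV with at least `sample_id`, `site`, `treatment`
#'   (one of `watered`, `drought`, `none`) and `class` (one of
#'   `experimental`, `mock`, `soil`).
#' @return tibble; an `imputed` logical column is added if absent.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  md <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("sample_id", "site", "treatment", "class")
  miss <- setdiff(needed, names(md))
  if (length(miss)) {
    rlang::abort(paste0("metadata lacks required columns: ",
                        paste(miss, collapse = ", ")))
  }
  bad_trt <- setdiff(unique(md$treatment), c("watered", "drought", "none"))
  if (length(bad_trt)) {
    rlang::abort(paste0("unknown treatment values: ",
                        paste(bad_trt, collapse = ", ")))
  }
  bad_cls <- setdiff(unique(md$class), c("experimental", "mock", "soil"))
  if (length(bad_cls)) {
    rlang::abort(paste0("unknown sample class values: ",
                        paste(bad_cls, collapse = ", ")))
  }
  if (is.null(md$imputed)) md$imputed <- FALSE
  md
}

#' Write a count table as a HUMAnN2-dialect gene-families TSV
#'
#' @param counts tibble, first column annotation IDs.
#' @param path output path.
#' @param humann_header write the first column as `# Gene Family`
#'   (default) rather than `annotation_id`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, humann_header = TRUE) {
  validate_counts(counts)
  out <- counts
  names(out)[1] <- if (humann_header) "# Gene Family" else "annotation_id"
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a ground-truth JSON written by [write_fixture_set()]
#'
#' @param path truth JSON path.
#' @return tibble with `annotation_id`, `label`, `log2fc`.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  tibble::as_tibble(jsonlite::fromJSON(path))
}
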