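# shared fixture builders; everything is generated in code at test time

tiny_counts <- function(mat, ids = NULL) {
  ids <- ids %||% paste0("g", seq_len(nrow(mat)))
  out <- tibble::as_tibble(as.data.frame(mat))
  if (is.null(colnames(mat))) names(out) <- paste0("S", seq_len(ncol(mat)))
  dplyr::bind_cols(tibble::tibble(annotation_id = ids), out)
}

tiny_metadata <- function(counts, treatment = NULL, class = NULL,
                          site = "CA") {
  ids <- names(counts)[-1]
  n <- length(ids)
  tibble::tibble(
    sample_id = ids,
    site = site,
    treatment = treatment %||% rep(c("watered", "drought"), length.out = n),
    class = class %||% rep("experimental", n),
    reads = 1e6,
    imputed = FALSE
  )
}

# null-model generator configs used in several files
null_config <- function(seed, n_annotations = 2000) {
  sim_config(n_annotations = n_annotations, frac_differential = 0,
             n_contaminants = 0, n_mock = 0, n_soil = 0, seed = seed)
}

# TMM offsets for a counts tibble (factor x library size, centered)
tmm_offsets <- function(counts) {
  f <- tmm_factors(counts)
  off <- log(f$factor * f$lib_size)
  stats::setNames(off - mean(off), f$sample_id)
}

treatment_of <- function(counts, metadata) {
  metadata$treatment[match(names(counts)[-1], metadata$sample_id)]
}

`%||%` <- rlang::`%||%`
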