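#' Simulation configuration for synthetic annotation count tables
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' The defaults describe a single field site with a two-group
#' (watered vs drought) design, three replicates per group, library
#' depths cycling through the read-depth classes observed in shallow
#' phyllosphere sequencing (150k / 350k / 1m / 2m reads), zero-inflated
#' negative binomial counts, 5\% truly differential annotations at
#' |log2 fold change| = 2, and 50 contaminant annotations that are also
#' present in mock/soil control columns.
#'
#' @param n_annotations number of non-contaminant annotation rows.
#' @param n_per_group experimental replicates per treatment group (>= 2).
#' @param library_reads per-sample sequencing depth in reads; recycled to
#'   `2 * n_per_group` samples. Expected column totals scale with depth.
#' @param frac_differential proportion of `n_annotations` that carry a
#'   true treatment effect, in \[0, 1\].
#' @param log2_fold_changes absolute log2 effect size(s) for differential
#'   annotations; recycled, signs assigned at random.
#' @param dispersion negative binomial dispersion phi > 0
#'   (variance = mu + phi * mu^2).
#' @param zero_inflation probability in \[0, 1) that any count cell is a
#'   structural zero, applied before the NB draw is observed.
#' @param n_contaminants number of contaminant annotations (>= 0). These
#'   appear in mock/soil columns *and* in experimental columns, so the
#'   contaminant filter has real work to do.
#' @param n_mock,n_soil number of mock / soil control columns.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of
#'   per-annotation baseline abundances (heavy-tailed rank-abundance).
#' @param control_reads depth of mock/soil columns, reads.
#' @param site field-site label stamped into the sample metadata.
#' @param seed integer seed; identical seeds give identical tables.
#'
#' @return a list of class `sim_config`.
#' @seealso [simulate_counts()], [write_fixture_set()]
#' @export
sim_config <- function(n_annotations = 2000,
                       n_per_group = 3,
                       library_reads = c(150e3, 350e3, 1e6, 2e6, 1e6, 350e3),
                       frac_differential = 0.05,
                       log2_fold_changes = 2,
                       dispersion = 0.2,
                       zero_inflation = 0.1,
                       n_contaminants = 50,
                       n_mock = 1,
                       n_soil = 1,
                       baseline_meanlog = log(100),
                       baseline_sdlog = 1.5,
                       control_reads = 150e3,
                       site = "CA",
                       seed = 1L) {
  check_scalar(n_annotations, "n_annotations", lower = 1, integerish = TRUE)
  check_scalar(n_per_group, "n_per_group", lower = 2, integerish = TRUE)
  check_scalar(frac_differential, "frac_differential", lower = 0, upper = 1)
  check_scalar(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  check_scalar(zero_inflation, "zero_inflation", lower = 0, upper = 1 - 1e-12)
  check_scalar(n_contaminants, "n_contaminants", lower = 0, integerish = TRUE)
  check_scalar(n_mock, "n_mock", lower = 0, integerish = TRUE)
  check_scalar(n_soil, "n_soil", lower = 0, integerish = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  if (any(!is.finite(library_reads)) || any(library_reads <= 0)) {
    rlang::abort("invalid `library_reads`: all library sizes must be strictly positive")
  }
  if (any(!is.finite(log2_fold_changes))) {
    rlang::abort("invalid `log2_fold_changes`: must be finite")
  }
  structure(
    list(
      n_annotations = as.integer(n_annotations),
      n_per_group = as.integer(n_per_group),
      library_reads = rep_len(library_reads, 2 * n_per_group),
      frac_differential = frac_differential,
      log2_fold_changes = log2_fold_changes,
      dispersion = dispersion,
      zero_inflation = zero_inflation,
      n_contaminants = as.integer(n_contaminants),
      n_mock = as.integer(n_mock),
      n_soil = as.integer(n_soil),
      baseline_meanlog = baseline_meanlog,
      baseline_sdlog = baseline_sdlog,
      control_reads = control_reads,
      site = site,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Generate a synthetic annotation-by-sample count table with known truth
#'
#' Draws a zero-inflated negative binomial count table under the design
#' described by a [sim_config()]: per-annotation baselines are log-normal,
#' expected counts are `baseline * (reads / 1e6) * 2^(lfc * drought)`,
#' counts are NB draws with the configured dispersion, and each cell is
#' independently zeroed with probability `zero_inflation`. Contaminant
#' annotations receive counts in the mock/soil control columns (at least
#' one nonzero control cell each) as well as in experimental columns;
#' non-contaminant annotations are absent from the controls.
#'
#' @param config a [sim_config()].
#' @return a list of class `phyllo_sim` with elements
#'   * `counts`: tibble, `annotation_id` + one column per sample;
#'   * `metadata`: tibble with `sample_id`, `site`, `treatment`
#'     (`watered`/`drought`/`none`), `class`
#'     (`experimental`/`mock`/`soil`), `reads`, `imputed`;
#'   * `truth`: tibble with `annotation_id`, `label`
#'     (`null`/`differential`/`contaminant`), `log2fc`, aligned
#'     row-for-row with `counts`;
#'   * `config`: the configuration used.
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) {
    rlang::abort("`config` must be created by sim_config()")
  }
  withr::with_seed(config$seed, {
    n_exp <- 2L * config$n_per_group
    trt <- rep(c("watered", "drought"), each = config$n_per_group)
    exp_ids <- sprintf("%s_%s_R%d", config$site,
                       ifelse(trt == "watered", "WW", "DR"),
                       rep(seq_len(config$n_per_group), times = 2))
    ctl_ids <- c(
      if (config$n_mock > 0) sprintf("mock%s_%d", config$site, seq_len(config$n_mock)),
      if (config$n_soil > 0) sprintf("soil%s_%d", config$site, seq_len(config$n_soil))
    )
    ctl_class <- c(rep("mock", config$n_mock), rep("soil", config$n_soil))

    n_sig <- as.integer(round(config$frac_differential * config$n_annotations))
    n_tot <- config$n_annotations + config$n_contaminants
    ann_ids <- sprintf("UniRef50_A%06d", seq_len(n_tot))

    label <- c(rep("differential", n_sig),
               rep("null", config$n_annotations - n_sig),
               rep("contaminant", config$n_contaminants))
    lfc <- numeric(n_tot)
    if (n_sig > 0) {
      mags <- rep_len(abs(config$log2_fold_changes), n_sig)
      lfc[seq_len(n_sig)] <- mags * sample(c(-1, 1), n_sig, replace = TRUE)
    }

    base <- rlnorm(n_tot, config$baseline_meanlog, config$baseline_sdlog)
    libf <- config$library_reads / 1e6
    drought <- as.numeric(trt == "drought")

    mu_exp <- outer(base, libf) * 2^(lfc %o% drought)
    y_exp <- matrix(rnbinom(length(mu_exp), mu = mu_exp,
                            size = 1 / config$dispersion),
                    nrow = n_tot)
    if (config$zero_inflation > 0) {
      y_exp[matrix(runif(length(mu_exp)) < config$zero_inflation,
                   nrow = n_tot)] <- 0L
    }

    n_ctl <- length(ctl_ids)
    y_ctl <- matrix(0L, nrow = n_tot, ncol = n_ctl)
    if (n_ctl > 0 && config$n_contaminants > 0) {
      cont <- which(label == "contaminant")
      mu_ctl <- outer(base[cont], rep(config$control_reads / 1e6, n_ctl))
      draws <- matrix(rnbinom(length(mu_ctl), mu = mu_ctl,
                              size = 1 / config$dispersion),
                      nrow = length(cont))
      if (config$zero_inflation > 0) {
        draws[matrix(runif(length(mu_ctl)) < config$zero_inflation,
                     nrow = length(cont))] <- 0L
      }
      # a contaminant must be observable in at least one control column
      all0 <- rowSums(draws > 0) == 0
      draws[all0, 1] <- 1L
      y_ctl[cont, ] <- draws
    }

    ord <- sample.int(n_tot)
    y <- cbind(y_exp, y_ctl)[ord, , drop = FALSE]
    rownames(y) <- ann_ids[ord]
    colnames(y) <- c(exp_ids, ctl_ids)

    metadata <- tibble::tibble(
      sample_id = c(exp_ids, ctl_ids),
      site = config$site,
      treatment = c(trt, rep("none", n_ctl)),
      class = c(rep("experimental", n_exp), ctl_class),
      reads = c(config$library_reads, rep(config$control_reads, n_ctl)),
      imputed = FALSE
    )
    truth <- tibble::tibble(
      annotation_id = ann_ids[ord],
      label = label[ord],
      log2fc = lfc[ord],
      seed = config$seed
    )
    structure(
      list(counts = matrix_counts(y), metadata = metadata,
           truth = truth, config = config),
      class = "phyllo_sim"
    )
  })
}

#' @export
print.phyllo_sim <- function(x, ...) {
  n_ctl <- sum(x$metadata$class != "experimental")
  cat(sprintf(
    "<phyllo_sim> %d annotations x %d samples (%d experimental, %d control)\n",
    nrow(x$counts), nrow(x$metadata), nrow(x$metadata) - n_ctl, n_ctl))
  cat(sprintf("  truth: %d differential, %d null, %d contaminant (seed %d)\n",
              sum(x$truth$label == "differential"),
              sum(x$truth$label == "null"),
              sum(x$truth$label == "contaminant"),
              x$config$seed))
  invisible(x)
}

#' Generate a synthetic many-to-many UniProt-to-GO mapping
#'
#' Assigns each annotation 0-4 GO terms (Poisson, mean ~1.3) from a pool
#' of synthetic term IDs in the `process` and `function` namespaces. The
#' construction guarantees at least one annotation with two or more terms
#' and at least one with none, mirroring the many-to-many, partly
#' unmapped character of real UniProt-to-GO conversions.
#'
#' @param annotation_ids character vector of annotation IDs to map.
#' @param n_terms size of the GO term pool.
#' @param seed integer seed.
#' @return tibble with columns `uniprot_id`, `go_id`, `namespace`.
#' @export
simulate_go_mapping <- function(annotation_ids, n_terms = 200, seed = 1L) {
  withr::with_seed(seed, {
    pool <- sprintf("GO:%07d", sample.int(9999999, n_terms))
    ns <- sample(c("process", "function"), n_terms, replace = TRUE)
    k <- stats::rpois(length(annotation_ids), 1.3)
    if (all(k == 0)) k[1] <- 2L
    if (!any(k >= 2)) k[which.max(k)] <- 2L
    if (!any(k == 0)) k[length(k)] <- 0L
    rows <- purrr::imap(k, function(ki, i) {
      if (ki == 0) return(NULL)
      idx <- sample.int(n_terms, min(ki, n_terms))
      tibble::tibble(uniprot_id = annotation_ids[i],
                     go_id = pool[idx], namespace = ns[idx])
    })
    dplyr::distinct(dplyr::bind_rows(rows))
  })
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits the four files the pipeline consumes: a count TSV in the
#' HUMAnN2 gene-families dialect, a sample-metadata CSV, a
#' UniProt-to-GO mapping TSV and a ground-truth JSON, plus a manifest.
#'
#' @param dir writable output directory (created if missing).
#' @param config a [sim_config()].
#' @return tibble manifest: file roles, paths, and the seed used.
#' @export
write_fixture_set <- function(dir, config = sim_config()) {
  sim <- simulate_counts(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) rlang::abort(paste0("cannot create directory: ", dir))
  paths <- c(
    counts = file.path(dir, "genefamilies.tsv"),
    metadata = file.path(dir, "metadata.csv"),
    go_mapping = file.path(dir, "uniprot_go.tsv"),
    truth = file.path(dir, "truth.json"),
    manifest = file.path(dir, "manifest.json")
  )
  write_count_table(sim$counts, paths[["counts"]])
  readr::write_csv(sim$metadata, paths[["metadata"]])
  mapping <- simulate_go_mapping(sim$truth$annotation_id, seed = config$seed)
  readr::write_tsv(mapping, paths[["go_mapping"]])
  jsonlite::write_json(sim$truth[c("annotation_id", "label", "log2fc")],
                       paths[["truth"]], digits = NA)
  manifest <- tibble::tibble(role = names(paths)[1:4],
                             path = unname(paths[1:4]),
                             seed = config$seed)
  jsonlite::write_json(manifest, paths[["manifest"]], digits = NA)
  manifest
}
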