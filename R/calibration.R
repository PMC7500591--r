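#' Confusion summary of significance calls against simulation truth
#'
#' Exact set arithmetic of a called significant set against the planted
#' truth labels. The annotation universe is the truth table minus
#' contaminant rows (those are removed by the filter before any test
#' sees them). `FDR = FP / (FP + TP)` and `power = TP / (TP + FN)`, both
#' defined as 0 when their denominator is 0 (no discoveries means no
#' false discoveries).
#'
#' @param calls character vector of called annotation IDs; must be a
#'   subset of the truth universe.
#' @param truth truth tibble (`annotation_id`, `label`, `log2fc`), e.g.
#'   from [simulate_counts()].
#' @return one-row tibble: `tp`, `fp`, `tn`, `fn`, `fdr`, `power`.
#' @export
confusion <- function(calls, truth) {
  calls <- unique(as.character(calls))
  unknown <- setdiff(calls, truth$annotation_id)
  if (length(unknown)) {
    rlang::abort(paste0("calls not present in truth: ",
                        paste(utils::head(unknown, 5), collapse = ", ")))
  }
  universe <- truth[truth$label != "contaminant", , drop = FALSE]
  bad <- setdiff(calls, universe$annotation_id)
  if (length(bad)) {
    rlang::abort(paste0("calls include contaminant-labelled annotations ",
                        "(filter before testing): ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  pos <- universe$annotation_id[universe$label == "differential"]
  tp <- sum(calls %in% pos)
  fp <- length(calls) - tp
  fn <- length(pos) - tp
  tn <- nrow(universe) - tp - fp - fn
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    fdr = if (tp + fp == 0) 0 else fp / (tp + fp),
    power = if (tp + fn == 0) 0 else tp / (tp + fn)
  )
}

#' Simulation grid for calibrating the significance threshold
#'
#' The validation harness: for each seed, generate a synthetic table
#' with known truth, contaminant-filter it, run the full two-stage
#' analysis under each normalization method, call significance at each
#' alpha, and tabulate the confusion matrix against the planted truth.
#' The per-(method, alpha) mean FDR and power over seeds are the basis
#' for choosing an operating threshold ([select_operating_point()]):
#' the realized FDR of the *whole* pipeline, selection step included, is
#' what this measures - the stage-2 p-values alone cannot be taken at
#' face value after data-driven screening.
#'
#' Stage-2 p-values do not depend on alpha, so each (seed, method)
#' pipeline run is thresholded at every alpha; results are identical to
#' rerunning per grid point, at a third of the cost.
#'
#' @param config base [sim_config()]; seeds `config$seed + 0:(n_seeds-1)`
#'   are used, so the whole grid is reproducible from the base seed.
#' @param alphas significance thresholds to evaluate.
#' @param methods normalization methods (`"tmm"`, `"deseq"`).
#' @param n_seeds simulated tables per grid point.
#' @param ... passed on to [run_ennb()] (e.g. `mixing`).
#' @return object of class `calibration_grid`: `$runs` is a tibble with
#'   one row per (seed, method, alpha) holding the confusion counts,
#'   `fdr`, `power`, and an `error` column for per-point failures (the
#'   grid keeps going when a stage fails). [glance()] gives per-point
#'   means; [tidy()] returns the runs.
#' @export
run_grid <- function(config = sim_config(),
                     alphas = c(0.05, 0.01, 0.001),
                     methods = c("tmm", "deseq"),
                     n_seeds = 25, ...) {
  if (!inherits(config, "sim_config")) {
    rlang::abort("`config` must be created by sim_config()")
  }
  if (!length(alphas) || !length(methods)) rlang::abort("empty grid")
  if (n_seeds < 1) rlang::abort("`n_seeds` must be >= 1")
  if (is.numeric(methods)) methods <- c("tmm", "deseq")[methods]

  seeds <- config$seed + seq_len(n_seeds) - 1L
  runs <- purrr::map(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    sim <- simulate_counts(cfg)
    filt <- filter_contaminants(sim$counts, sim$metadata)
    purrr::map(methods, function(m) {
      fit <- tryCatch(
        run_ennb(filt$counts, filt$metadata, method = m,
                 alpha = min(alphas), seed = s, ...),
        error = function(e) e
      )
      purrr::map(alphas, function(a) {
        if (inherits(fit, "error")) {
          return(tibble::tibble(seed = s, method = m, alpha = a,
                                tp = NA_integer_, fp = NA_integer_,
                                tn = NA_integer_, fn = NA_integer_,
                                fdr = NA_real_, power = NA_real_,
                                error = conditionMessage(fit)))
        }
        calls <- significant_annotations(fit, alpha = a)
        cs <- confusion(calls, sim$truth)
        dplyr::bind_cols(tibble::tibble(seed = s, method = m, alpha = a),
                         cs, tibble::tibble(error = NA_character_))
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  n_failed <- sum(!is.na(runs$error)) / length(alphas)
  if (n_failed > 0) {
    rlang::warn(sprintf("%d pipeline run(s) failed; see the error column",
                        as.integer(n_failed)))
  }
  structure(list(runs = runs, config = config, alphas = alphas,
                 methods = methods, n_seeds = n_seeds),
            class = "calibration_grid")
}

#' @export
print.calibration_grid <- function(x, ...) {
  cat(sprintf("<calibration_grid> %d seeds x %d methods x %d alphas\n",
              x$n_seeds, length(x$methods), length(x$alphas)))
  print(glance(x))
  invisible(x)
}

# per-(method, alpha) mean confusion statistics
grid_means <- function(grid) {
  grid$runs |>
    dplyr::filter(is.na(error)) |>
    dplyr::group_by(method, alpha) |>
    dplyr::summarise(n_runs = dplyr::n(),
                     mean_fdr = mean(fdr),
                     mean_power = mean(power),
                     .groups = "drop") |>
    dplyr::arrange(method, alpha)
}

#' Pick the operating point of the calibration grid
#'
#' Returns the grid point with the lowest mean FDR among points whose
#' mean power reaches `power_floor`; ties break toward the smaller alpha
#' and then toward TMM normalization. When no point reaches the floor,
#' the unconstrained FDR minimizer is returned with a warning.
#'
#' @param grid a `calibration_grid`.
#' @param power_floor minimum acceptable mean power (default 0.05).
#' @return one-row tibble: `method`, `alpha`, `mean_fdr`, `mean_power`.
#' @export
select_operating_point <- function(grid, power_floor = 0.05) {
  stopifnot(inherits(grid, "calibration_grid"))
  means <- grid_means(grid)
  if (!nrow(means)) rlang::abort("grid contains no successful runs")
  candidates <- means[means$mean_power >= power_floor, , drop = FALSE]
  if (!nrow(candidates)) {
    rlang::warn("no grid point reaches the power floor; returning global FDR minimizer")
    candidates <- means
  }
  candidates <- candidates[order(candidates$mean_fdr,
                                 candidates$alpha,
                                 candidates$method != "tmm"), , drop = FALSE]
  candidates[1, c("method", "alpha", "mean_fdr", "mean_power")]
}
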