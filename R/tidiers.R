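#' Tidy a fitted two-stage differential analysis
#'
#' @param x an `ennb_fit` from [run_ennb()].
#' @param ... unused.
#' @return the per-annotation results tibble.
#' @exportS3Method
tidy.ennb_fit <- function(x, ...) {
  x$results
}

#' One-row summary of a fitted two-stage differential analysis
#'
#' @param x an `ennb_fit`.
#' @param ... unused.
#' @return tibble: site, normalization method, alpha, lambda, counts of
#'   analyzed / selected / significant annotations.
#' @exportS3Method
glance.ennb_fit <- function(x, ...) {
  tibble::tibble(
    site = x$site, method = x$method, alpha = x$alpha,
    lambda = x$lambda, mixing = x$mixing, seed = x$seed,
    n_annotations = nrow(x$results),
    n_selected = sum(x$results$selected),
    n_significant = sum(x$results$significant),
    n_dropped = x$n_dropped
  )
}

#' Tidy a calibration grid
#'
#' @param x a `calibration_grid` from [run_grid()].
#' @param ... unused.
#' @return tibble of per-(seed, method, alpha) confusion rows.
#' @exportS3Method
tidy.calibration_grid <- function(x, ...) {
  x$runs
}

#' Per-grid-point means of a calibration grid
#'
#' @param x a `calibration_grid`.
#' @param ... unused.
#' @return tibble with `method`, `alpha`, `n_runs`, `mean_fdr`,
#'   `mean_power`.
#' @exportS3Method
glance.calibration_grid <- function(x, ...) {
  grid_means(x)
}

#' Tidy a plant-trait fit
#'
#' @param x a `trait_fit` from [fit_trait()].
#' @param ... unused.
#' @return one-row tibble with the treatment-effect estimate
#'   (watered minus drought), SE, p-value, group means and sizes.
#' @exportS3Method
tidy.trait_fit <- function(x, ...) {
  tibble::tibble(
    trait = paste(x$trait_name, collapse = "/"),
    estimate = x$estimate, se = x$se, p_value = x$p_value,
    significant = x$significant,
    mean_watered = x$means[[x$levels[1]]],
    mean_drought = x$means[[x$levels[2]]],
    n_watered = x$ns[[x$levels[1]]],
    n_drought = x$ns[[x$levels[2]]],
    percent_reduction = x$percent_reduction
  )
}

#' Model-level summary of a plant-trait fit
#'
#' @param x a `trait_fit`.
#' @param ... unused.
#' @return one-row tibble with r.squared, sigma, residual df and the
#'   blocks flag.
#' @exportS3Method
glance.trait_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    r_squared = s$r.squared, sigma = s$sigma,
    df_residual = x$model$df.residual,
    include_blocks = x$include_blocks
  )
}
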