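#' Simulate a two-group plant-trait table with known treatment effect
#'
#' Stand-in generator for field trait measurements (plant height, seed
#' weight, cob diameter): normal trait values with a known watered-minus-
#' drought mean difference, plants assigned round-robin to plots within
#' treatment, and optional plot-level random shifts.
#'
#' @param n_per_group plants per treatment group (>= 2).
#' @param effect true mean reduction under drought, in trait units
#'   (positive = drought smaller).
#' @param sd residual standard deviation (> 0).
#' @param baseline watered-group mean.
#' @param trait_name,units trait labelling (default height in meters).
#' @param site site label.
#' @param n_plots plots per treatment (blocks).
#' @param plot_sd standard deviation of plot-level shifts (default 0).
#' @param seed integer seed.
#' @return tibble: `site`, `plot_id`, `treatment`, `trait_name`, `value`,
#'   `units`.
#' @export
simulate_traits <- function(n_per_group, effect, sd, baseline = 2,
                            trait_name = "height", units = "m",
                            site = "CA", n_plots = 3, plot_sd = 0,
                            seed = 1L) {
  check_scalar(n_per_group, "n_per_group", lower = 2, integerish = TRUE)
  check_scalar(sd, "sd", lower = 0, strict_lower = TRUE)
  check_scalar(n_plots, "n_plots", lower = 1, integerish = TRUE)
  withr::with_seed(seed, {
    trt <- rep(c("watered", "drought"), each = n_per_group)
    plot_id <- c(100 + rep_len(seq_len(n_plots), n_per_group),
                 200 + rep_len(seq_len(n_plots), n_per_group))
    shifts <- setNames(rnorm(2 * n_plots, 0, plot_sd),
                       c(100 + seq_len(n_plots), 200 + seq_len(n_plots)))
    mu <- ifelse(trt == "drought", baseline - effect, baseline) +
      shifts[as.character(plot_id)]
    tibble::tibble(
      site = site, plot_id = plot_id, treatment = trt,
      trait_name = trait_name,
      value = rnorm(2 * n_per_group, mu, sd),
      units = units
    )
  })
}

#' Exclude trait rows by declarative rule
#'
#' Applies the documented exclusions used in field-trait analyses - e.g.
#' dropping zero-value records (cobs that set no seed) or whole plots
#' invalidated by events such as unmanaged late-season rain - and keeps
#' an audit of what was removed.
#'
#' @param data trait tibble (see [simulate_traits()] for columns).
#' @param drop_zero remove rows with `value == 0`.
#' @param drop_plots plot IDs to remove entirely.
#' @param predicate optional function of the data frame returning a
#'   logical keep-vector, for ad-hoc rules.
#' @return the filtered tibble; removed rows are attached as
#'   `attr(, "removed")`. Removing every row of a treatment level is an
#'   error (the analysis would lose its contrast).
#' @export
exclude_rows <- function(data, drop_zero = FALSE, drop_plots = NULL,
                         predicate = NULL) {
  stopifnot(is.data.frame(data))
  keep <- rep(TRUE, nrow(data))
  if (drop_zero) keep <- keep & data$value != 0
  if (!is.null(drop_plots)) keep <- keep & !(data$plot_id %in% drop_plots)
  if (!is.null(predicate)) keep <- keep & predicate(data)
  lost <- setdiff(unique(data$treatment), unique(data$treatment[keep]))
  if (length(lost)) {
    rlang::abort(paste0("exclusion removed every row of treatment level: ",
                        paste(lost, collapse = ", ")))
  }
  out <- data[keep, , drop = FALSE]
  removed <- data[!keep, , drop = FALSE]
  if (nrow(removed)) {
    rlang::inform(sprintf("excluded %d of %d rows", nrow(removed), nrow(data)))
  }
  attr(out, "removed") <- removed
  out
}

#' Treatment-effect estimate for a plant trait
#'
#' Ordinary least squares of trait value on water treatment (nominal),
#' optionally with plot IDs as fixed blocks. The effect is reported as
#' the watered-minus-drought difference (positive = drought smaller),
#' with its standard error, two-sided p-value, group means and sizes,
#' and the percent reduction relative to the watered mean. With balanced
#' groups and no blocks the estimate equals the difference of group
#' means exactly.
#'
#' @param data trait tibble with `treatment` and `value` columns (and
#'   `plot_id` when `include_blocks = TRUE`). If several traits are
#'   present, pass `trait` to pick one.
#' @param trait optional `trait_name` to filter on.
#' @param include_blocks add `factor(plot_id)` block terms.
#' @param alpha significance level for the convenience flag.
#' @return object of class `trait_fit` with `estimate`, `se`, `p_value`,
#'   `significant`, `means`, `ns`, `percent_reduction`, and the
#'   underlying `lm` fit. [tidy()] / [glance()] methods available.
#' @export
fit_trait <- function(data, trait = NULL, include_blocks = FALSE,
                      alpha = 0.05) {
  stopifnot(is.data.frame(data))
  if (!is.null(trait)) {
    data <- data[data$trait_name == trait, , drop = FALSE]
    if (!nrow(data)) rlang::abort(paste0("no rows for trait: ", trait))
  }
  if (any(!is.finite(data$value))) rlang::abort("trait values must be finite")
  lev <- sort(unique(data$treatment))
  if (length(lev) != 2) {
    rlang::abort("treatment must have exactly 2 levels in the analysis set")
  }
  if (setequal(lev, c("watered", "drought"))) lev <- c("watered", "drought")
  data$treatment <- factor(data$treatment, levels = lev)
  ns <- table(data$treatment)
  if (any(ns < 2)) rlang::abort("need >= 2 observations per treatment level")

  fml <- if (include_blocks) value ~ treatment + factor(plot_id) else value ~ treatment
  fit <- lm(fml, data = data)
  term <- paste0("treatment", lev[2])
  aliased <- is.na(coef(fit))
  if (include_blocks) {
    plot_terms <- grep("^factor\\(plot_id\\)", names(aliased), value = TRUE)
    # with plots nested in treatment, one plot dummy per treatment level
    # is absorbed and the treatment contrast remains estimable; if EVERY
    # plot dummy is aliased the blocks are fully confounded with treatment
    if (length(plot_terms) && all(aliased[plot_terms])) {
      rlang::abort(paste0(
        "singular block structure: blocks fully confounded with treatment (",
        paste(sort(unique(data$plot_id)), collapse = ", "), ")"))
    }
  }
  if (aliased[[term]]) {
    rlang::abort("singular block structure: treatment is not estimable")
  }
  cf <- summary(fit)$coefficients
  beta <- cf[term, "Estimate"]
  # report as reduction under the non-baseline (drought) level
  estimate <- -beta
  se <- cf[term, "Std. Error"]
  p <- cf[term, "Pr(>|t|)"]
  means <- tapply(data$value, data$treatment, mean)
  structure(
    list(estimate = unname(estimate), se = unname(se), p_value = unname(p),
         significant = p < alpha, alpha = alpha,
         means = means, ns = c(ns),
         percent_reduction = unname(100 * estimate / means[[lev[1]]]),
         levels = lev, include_blocks = include_blocks,
         trait_name = unique(data$trait_name) %||% NA_character_,
         units = unique(data$units) %||% NA_character_,
         model = fit),
    class = "trait_fit"
  )
}

#' @export
print.trait_fit <- function(x, ...) {
  cat(sprintf("<trait_fit> %s: %s - %s difference = %.4g %s (SE %.3g, p = %.3g)\n",
              paste(x$trait_name, collapse = "/"),
              x$levels[1], x$levels[2], x$estimate,
              paste(x$units, collapse = "/"), x$se, x$p_value))
  cat(sprintf("  group means: %s = %.4g (n = %d), %s = %.4g (n = %d); %.1f%% reduction\n",
              x$levels[1], x$means[[x$levels[1]]], x$ns[[x$levels[1]]],
              x$levels[2], x$means[[x$levels[2]]], x$ns[[x$levels[2]]],
              x$percent_reduction))
  invisible(x)
}
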