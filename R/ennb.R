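#' Elastic-net screening of candidate differential annotations
#'
#' Stage 1 of the two-stage differential test. Annotation abundances are
#' normalized, transformed to `log(normalized + 1)` and standardized;
#' an elastic-net regression of the treatment indicator (coded 0/1, a
#' gaussian working response) on the annotation matrix is fitted over a
#' lambda path, and the cross-validated lambda's nonzero coefficients
#' define the selected set. With a handful of samples and thousands of
#' annotations the penalty must lean heavily on its ridge component: the
#' grouping effect then spreads weight across correlated true
#' predictors instead of picking one representative, which is what makes
#' the screen sensitive (default `mixing = 0.01`). Cross-validation is
#' leave-one-out when there are at most 8 samples, else 5-fold, with
#' fold assignment fixed by `seed`.
#'
#' @param counts count tibble (experimental samples only).
#' @param treatment per-sample treatment labels (two levels, e.g.
#'   `watered` / `drought`), aligned with the sample columns.
#' @param size_factors optional factor tibble from [tmm_factors()] or
#'   [deseq_size_factors()]; default is column-total scaling.
#' @param mixing elastic-net mixing parameter in \[0, 1\]
#'   (0 = ridge, 1 = lasso).
#' @param lambda `"lambda.min"` (default), `"lambda.1se"`, or a numeric
#'   penalty to use directly (skips cross-validation).
#' @param n_folds cross-validation folds; default: leave-one-out when
#'   n <= 8, else 5.
#' @param seed integer seed controlling fold assignment.
#' @param lambda_min_ratio smallest lambda on the path, as a fraction of
#'   the largest.
#' @return list of class `ennb_selection`: `selected` (character IDs),
#'   `lambda`, `mixing`, `n_folds`, `seed`, and `coefficients`
#'   (tibble of nonzero coefficients on the standardized scale).
#' @export
elastic_net_select <- function(counts, treatment, size_factors = NULL,
                               mixing = 0.01, lambda = "lambda.min",
                               n_folds = NULL, seed = 1L,
                               lambda_min_ratio = 1e-4) {
  validate_counts(counts)
  m <- counts_matrix(counts)
  n <- ncol(m)
  treatment <- as.character(treatment)
  if (length(treatment) != n) {
    rlang::abort("`treatment` must have one label per sample column")
  }
  y <- treatment_indicator(treatment)$g
  if (min(table(treatment)) < 3) {
    rlang::abort("fewer than 3 samples per group: impute a replicate first (see impute_replicate)")
  }
  if (mixing < 0 || mixing > 1) rlang::abort("`mixing` must be in [0, 1]")

  sf <- normalization_scale(size_factors, m)
  x <- t(log(sweep(m, 2, sf, "/") + 1))
  keep <- apply(x, 2, var) > 0
  if (!any(keep)) {
    rlang::warn("all annotations constant across samples; nothing to select")
    return(new_ennb_selection(character(0), NA_real_, mixing, NA_integer_,
                              seed, tibble::tibble(annotation_id = character(0),
                                                   coefficient = numeric(0))))
  }
  xs <- scale(x[, keep, drop = FALSE])
  ids <- rownames(m)[keep]

  if (is.numeric(lambda)) {
    fit <- glmnet::glmnet(xs, y, family = "gaussian", alpha = mixing,
                          standardize = FALSE,
                          lambda.min.ratio = lambda_min_ratio)
    co <- as.numeric(coef(fit, s = lambda))[-1]
    return(new_ennb_selection(ids[co != 0], lambda, mixing, NA_integer_, seed,
                              tibble::tibble(annotation_id = ids[co != 0],
                                             coefficient = co[co != 0])))
  }

  n_folds <- n_folds %||% (if (n <= 8) n else 5L)
  foldid <- if (n_folds >= n) {
    seq_len(n)
  } else {
    withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  }
  cv <- suppressWarnings(glmnet::cv.glmnet(
    xs, y, family = "gaussian", alpha = mixing, foldid = foldid,
    grouped = FALSE, standardize = FALSE,
    lambda.min.ratio = lambda_min_ratio))
  s <- match.arg(lambda, c("lambda.min", "lambda.1se"))
  lam <- cv[[s]]
  co <- as.numeric(coef(cv, s = s))[-1]
  new_ennb_selection(ids[co != 0], lam, mixing, as.integer(n_folds), seed,
                     tibble::tibble(annotation_id = ids[co != 0],
                                    coefficient = co[co != 0]))
}

new_ennb_selection <- function(selected, lambda, mixing, n_folds, seed, coefs) {
  structure(list(selected = selected, lambda = lambda, mixing = mixing,
                 n_folds = n_folds, seed = seed, coefficients = coefs),
            class = "ennb_selection")
}

#' @export
print.ennb_selection <- function(x, ...) {
  cat(sprintf("<ennb_selection> %d annotations selected (lambda = %.4g, mixing = %g)\n",
              length(x$selected), x$lambda, x$mixing))
  invisible(x)
}

# scale vector used to normalize counts for the elastic-net transform
normalization_scale <- function(size_factors, m) {
  if (is.null(size_factors)) {
    libs <- colSums(m)
    if (any(libs == 0)) rlang::abort("sample with all-zero counts")
    return(libs / geometric_mean(libs))
  }
  sf <- setNames(size_factors$factor, size_factors$sample_id)[colnames(m)]
  if (any(is.na(sf))) rlang::abort("size_factors do not cover all samples")
  if (size_factors$method[1] == "tmm") {
    eff <- sf * setNames(size_factors$lib_size,
                         size_factors$sample_id)[colnames(m)]
    return(eff / geometric_mean(eff))
  }
  sf / geometric_mean(sf)
}

#' Per-annotation negative binomial treatment test
#'
#' Stage 2 of the two-stage differential test: for each annotation, a
#' negative binomial GLM with log link, the treatment indicator as the
#' sole factor and a per-sample log-offset (normalization factor x
#' library size). The Wald statistic on the treatment coefficient is
#' referenced against the normal (default) or a t distribution.
#'
#' Dispersion: a per-annotation method-of-moments estimate, pooled
#' within groups on offset-adjusted counts, moderated by weight
#' `prior_weight` toward the common (across-annotation mean) dispersion
#' and floored at `dispersion_floor`. Three-per-group designs cannot
#' support per-annotation maximum likelihood dispersion; moderation
#' stabilises the far tail of the null. The Wald standard error uses the
#' specified NB variance as-is (no Pearson rescaling: with 4 residual
#' degrees of freedom a rescaled SE collapses for annotations whose
#' within-group spread is coincidentally tiny, flooding the far tail
#' with false positives).
#'
#' @param counts count tibble, matrix, or a single annotation's numeric
#'   vector of counts.
#' @param treatment per-sample treatment labels (two levels). With
#'   `watered`/`drought` labels the coefficient is the log fold change of
#'   drought over watered; otherwise the second sorted level over the
#'   first.
#' @param offsets per-sample log offsets (e.g. from normalization);
#'   default `0` for all samples.
#' @param dispersion optional fixed dispersion phi (scalar or one per
#'   annotation); overrides estimation.
#' @param prior_weight moderation weight toward the common dispersion,
#'   in \[0, 1\] (default 0.3).
#' @param dispersion_floor lower bound for the moderated dispersion.
#' @param df degrees of freedom of the Wald reference distribution
#'   (`Inf` = normal, the default).
#' @return tibble with one row per annotation: `annotation_id`,
#'   `estimate` (natural-log fold change), `log2_fc`, `se`, `statistic`,
#'   `p_value`, `dispersion`, `converged`. Non-converged fits are
#'   returned with `p_value = 1` and a warning, never an error.
#' @export
nb_test <- function(counts, treatment, offsets = NULL, dispersion = NULL,
                    prior_weight = 0.3, dispersion_floor = 1e-8, df = Inf) {
  if (is.numeric(counts) && is.null(dim(counts))) {
    m <- matrix(counts, nrow = 1, dimnames = list("annotation_1", NULL))
  } else if (is.matrix(counts)) {
    m <- counts
    if (is.null(rownames(m))) {
      rownames(m) <- paste0("annotation_", seq_len(nrow(m)))
    }
  } else {
    validate_counts(counts)
    m <- counts_matrix(counts)
  }
  n <- ncol(m)
  treatment <- as.character(treatment)
  if (length(treatment) != n) {
    rlang::abort("`treatment` must have one label per sample")
  }
  if (min(table(treatment)) < 3) {
    rlang::abort("fewer than 3 samples per group: impute a replicate first (see impute_replicate)")
  }
  g <- treatment_indicator(treatment)$g
  off <- offsets %||% rep(0, n)
  if (!is.null(names(off))) off <- off[colnames(m)]
  if (length(off) != n || any(!is.finite(off))) {
    rlang::abort("`offsets` must be finite, one per sample")
  }

  phi <- if (!is.null(dispersion)) {
    if (any(dispersion <= 0)) rlang::abort("`dispersion` must be positive")
    rep_len(dispersion, nrow(m))
  } else {
    moderated_dispersion(m, g, off, prior_weight, dispersion_floor)
  }

  fits <- nb_fit_rows(m, g, off, phi, df)
  if (any(!fits$converged)) {
    rlang::warn(sprintf("%d annotation fit(s) did not converge; p set to 1",
                        sum(!fits$converged)))
  }
  fits
}

# method-of-moments dispersion pooled within groups on offset-adjusted
# counts, moderated toward the across-annotation mean
moderated_dispersion <- function(m, g, off, prior_weight, floor) {
  adj <- sweep(m, 2, exp(off), "/")
  per_gene <- apply(adj, 1, function(r) {
    mg <- tapply(r, g, mean)
    vg <- tapply(r, g, var)
    ph <- (vg - mg) / mg^2
    ph <- ph[is.finite(ph)]
    if (!length(ph)) return(NA_real_)
    mean(ph)
  })
  common <- mean(pmax(per_gene, 0), na.rm = TRUE)
  if (!is.finite(common)) common <- floor
  per_gene[is.na(per_gene)] <- common
  pmax((1 - prior_weight) * per_gene + prior_weight * common, floor)
}

# row-wise NB GLM fits at fixed dispersion; Wald p on the group term
nb_fit_rows <- function(m, g, off, phi, df) {
  out <- tibble::tibble(
    annotation_id = rownames(m),
    estimate = NA_real_, log2_fc = NA_real_, se = NA_real_,
    statistic = NA_real_, p_value = 1, dispersion = phi, converged = FALSE
  )
  for (i in seq_len(nrow(m))) {
    fam <- MASS::negative.binomial(theta = 1 / phi[i])
    fit <- tryCatch(
      suppressWarnings(glm(m[i, ] ~ g + offset(off), family = fam)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) next
    cf <- tryCatch(
      suppressWarnings(summary(fit, dispersion = 1)$coefficients),
      error = function(e) NULL
    )
    if (is.null(cf) || nrow(cf) < 2 || !all(is.finite(cf["g", 1:2]))) next
    b <- cf["g", 1]
    s <- cf["g", 2]
    out$estimate[i] <- b
    out$log2_fc[i] <- b / log(2)
    out$se[i] <- s
    out$statistic[i] <- b / s
    out$p_value[i] <- 2 * pt(-abs(b / s), df = df)
    out$converged[i] <- TRUE
  }
  out
}

#' Run the two-stage differential-abundance analysis for one site
#'
#' The full per-site procedure: normalize (TMM or DESeq-type size
#' factors), screen candidate annotations with an elastic net
#' ([elastic_net_select()]), then test only the screened annotations
#' with per-annotation negative binomial GLMs ([nb_test()]) and call
#' significance at `alpha`. No multiple-testing correction is applied:
#' the operating threshold is meant to be calibrated by simulation
#' ([run_grid()]), which measures the realized false discovery rate of
#' the whole two-stage procedure including the selection step.
#'
#' The table must already be contaminant-filtered
#' ([filter_contaminants()]) and contain a single site: per-site
#' analysis is the unit of inference because sites differ in irrigation
#' protocol, soil and climate. Annotations with all-zero or
#' all-identical counts are dropped before fitting (counted in the
#' provenance).
#'
#' @param counts contaminant-filtered count tibble (experimental
#'   samples only).
#' @param metadata sample metadata covering the sample columns.
#' @param method normalization method: `"tmm"` / `1` or `"deseq"` / `2`.
#' @param alpha significance threshold on the stage-2 p-value.
#' @param seed integer seed (elastic-net fold assignment).
#' @param mixing,lambda stage-1 controls, see [elastic_net_select()].
#' @param prior_weight,df stage-2 controls, see [nb_test()].
#' @return object of class `ennb_fit`. `$results` is a tibble over all
#'   analyzable annotations: `annotation_id`, `selected`, `estimate`,
#'   `log2_fc`, `se`, `p_value`, `significant` (stage-2 columns are `NA`
#'   for unselected annotations). Provenance (method, alpha, lambda,
#'   mixing, seed, dropped-row counts, normalization factors) is stored
#'   alongside. [tidy()] and [glance()] methods are available.
#' @export
run_ennb <- function(counts, metadata, method = c("tmm", "deseq"),
                     alpha = 0.001, seed = 1L, mixing = 0.01,
                     lambda = "lambda.min", prior_weight = 0.3, df = Inf) {
  if (is.numeric(method)) method <- c("tmm", "deseq")[method]
  method <- match.arg(method)
  validate_counts(counts, metadata)
  md <- aligned_metadata(counts, metadata)
  if (any(md$class != "experimental")) {
    rlang::abort("control samples present: run filter_contaminants() first")
  }
  sites <- unique(md$site)
  if (length(sites) > 1) {
    rlang::abort(paste0("mixed sites in input (", paste(sites, collapse = ", "),
                        "): analysis is per-site"))
  }
  if (!alpha >= 0 || !alpha <= 1) rlang::abort("`alpha` must be in [0, 1]")

  m <- counts_matrix(counts)
  zero_rows <- rowSums(m) == 0
  const_rows <- !zero_rows & apply(m, 1, function(r) all(r == r[1]))
  n_dropped <- sum(zero_rows | const_rows)
  if (n_dropped > 0) {
    rlang::inform(sprintf(
      "dropping %d all-zero and %d constant annotation row(s) before fitting",
      sum(zero_rows), sum(const_rows)))
  }
  kept <- counts[!(zero_rows | const_rows), , drop = FALSE]
  mk <- counts_matrix(kept)

  factors <- switch(method,
                    tmm = tmm_factors(kept),
                    deseq = deseq_size_factors(kept))
  offs <- norm_offsets(factors)

  sel <- elastic_net_select(kept, md$treatment, size_factors = factors,
                            mixing = mixing, lambda = lambda, seed = seed)

  # stage 2 is nb_test() on the screened subtable: dispersion moderation
  # is estimated within the tested population
  coding <- treatment_indicator(md$treatment)
  g <- coding$g
  results <- tibble::tibble(annotation_id = rownames(mk),
                            selected = rownames(mk) %in% sel$selected)
  if (length(sel$selected)) {
    idx <- match(sel$selected, rownames(mk))
    phi_sel <- moderated_dispersion(mk[idx, , drop = FALSE], g,
                                    offs[colnames(mk)], prior_weight, 1e-8)
    tested <- nb_fit_rows(mk[idx, , drop = FALSE], g, offs[colnames(mk)],
                          phi_sel, df)
    results <- dplyr::left_join(results, tested, by = "annotation_id")
  } else {
    results$estimate <- NA_real_
    results$log2_fc <- NA_real_
    results$se <- NA_real_
    results$statistic <- NA_real_
    results$p_value <- NA_real_
    results$dispersion <- NA_real_
    results$converged <- NA
  }
  results$significant <- results$selected &
    !is.na(results$p_value) & results$p_value < alpha

  structure(
    list(results = results, method = method, alpha = alpha,
         lambda = sel$lambda, mixing = mixing, seed = seed,
         site = sites, n_samples = ncol(mk),
         n_dropped = n_dropped, norm_factors = factors,
         treatment_levels = coding$levels),
    class = "ennb_fit"
  )
}

#' @export
print.ennb_fit <- function(x, ...) {
  cat(sprintf("<ennb_fit> site %s, %s normalization, alpha = %g\n",
              x$site, x$method, x$alpha))
  cat(sprintf("  %d annotations analyzed, %d selected, %d significant\n",
              nrow(x$results), sum(x$results$selected),
              sum(x$results$significant)))
  cat(sprintf("  log fold changes are %s relative to %s\n",
              x$treatment_levels[2], x$treatment_levels[1]))
  invisible(x)
}

#' Significant annotation IDs from a fitted two-stage analysis
#'
#' @param fit an `ennb_fit`.
#' @param alpha optional override of the fit's threshold.
#' @return character vector of annotation IDs.
#' @export
significant_annotations <- function(fit, alpha = NULL) {
  stopifnot(inherits(fit, "ennb_fit"))
  a <- alpha %||% fit$alpha
  r <- fit$results
  r$annotation_id[r$selected & !is.na(r$p_value) & r$p_value < a]
}
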