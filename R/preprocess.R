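#' Filter metabolites by measurability
#'
#' Keeps metabolites quantified in at least `min_fraction` of samples.
#' "Measurable" counts genuinely quantified entries only: below-LOD and
#' missing entries both count against a metabolite, since both are
#' detection failures.
#'
#' @param table A [sample_table()].
#' @param min_fraction Minimum measurable fraction, inclusive (default 0.8).
#' @return The filtered `sample_table`; dropped metabolite names are
#'   attached as attribute `"dropped"` and reported via a message.
#' @export
filter_metabolites <- function(table, min_fraction = 0.8) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  st <- status_matrix(table)
  frac <- colMeans(st == "quantified" | st == "imputed_lod" |
                     st == "imputed_mean")
  keep <- frac >= min_fraction
  if (!any(keep)) {
    abort("all metabolites fall below the measurability threshold; review min_fraction")
  }
  dropped <- names(frac)[!keep]
  if (length(dropped) > 0) {
    inform(paste0("filter_metabolites: dropped ", length(dropped),
                  " metabolite(s): ", paste(dropped, collapse = ", ")))
  }
  vals <- metabolite_matrix(table)[, keep, drop = FALSE]
  out <- set_values(table, vals, st[, keep, drop = FALSE])
  attr(out, "dropped") <- dropped
  out
}

#' Impute below-LOD entries at half the minimum quantified level
#'
#' Every below-LOD entry of a metabolite is replaced by half the minimum
#' quantified concentration of that metabolite, both groups pooled. The
#' entry's status becomes `"imputed_lod"`.
#'
#' @param table A [sample_table()].
#' @return The imputed `sample_table`.
#' @export
impute_below_lod <- function(table) {
  st <- status_matrix(table)
  vals <- metabolite_matrix(table)
  for (m in colnames(vals)) {
    lod <- st[, m] == "below_lod"
    if (!any(lod)) next
    q <- vals[st[, m] %in% c("quantified", "imputed_mean"), m]
    q <- q[!is.na(q)]
    if (length(q) == 0) {
      abort(paste0("metabolite '", m, "' has no quantified entries; ",
                   "half-minimum LOD imputation is undefined"))
    }
    vals[lod, m] <- 0.5 * min(q)
    st[lod, m] <- "imputed_lod"
  }
  set_values(table, vals, st)
}

#' Residualise metabolite levels against covariates
#'
#' Replaces each metabolite column by the residuals of an ordinary
#' least-squares regression on an intercept plus the named covariates,
#' fitted on both groups pooled (adjustment is performed once, prior to
#' any group comparison, and is group-blind). Entries flagged missing are
#' excluded from each fit and remain missing afterwards.
#'
#' @param table A [sample_table()] (below-LOD entries already imputed).
#' @param covariates Covariate names; default all four of
#'   [cohort_covariates()].
#' @return The residualised `sample_table`. Residuals of every metabolite
#'   have zero sample correlation with every covariate (to numerical
#'   precision) on the samples used in the fit.
#' @export
adjust_covariates <- function(table, covariates = cohort_covariates()) {
  stopifnot(all(covariates %in% names(table)))
  st <- status_matrix(table)
  vals <- metabolite_matrix(table)
  design <- cbind(`(Intercept)` = 1,
                  as.matrix(as_tibble(table)[covariates]))
  if (qr(design)$rank < ncol(design)) {
    abort(paste0("covariate design is rank deficient; check for collinear ",
                 "covariates among: ", paste(covariates, collapse = ", ")))
  }
  if (nrow(design) < ncol(design)) {
    abort("fewer samples than regression parameters")
  }
  for (m in colnames(vals)) {
    ok <- !is.na(vals[, m])
    fit <- stats::lm.fit(design[ok, , drop = FALSE], vals[ok, m])
    vals[ok, m] <- fit$residuals
  }
  set_values(table, vals, st)
}

#' Mean-impute missing entries
#'
#' Metabolites missing in fewer than `max_missing` of samples have each
#' missing entry replaced by the all-sample mean of the metabolite; the
#' status becomes `"imputed_mean"`. Metabolites at or above the bound are
#' dropped with a warning.
#'
#' @param table A [sample_table()].
#' @param max_missing Per-metabolite missingness bound (default 0.05,
#'   exclusive: metabolites with >= 5% missing are dropped).
#' @return The imputed `sample_table`.
#' @export
impute_missing <- function(table, max_missing = 0.05) {
  st <- status_matrix(table)
  vals <- metabolite_matrix(table)
  frac <- colMeans(st == "missing")
  drop <- frac >= max_missing
  if (any(drop)) {
    warn(paste0("impute_missing: dropped ", sum(drop),
                " metabolite(s) with >= ", max_missing * 100, "% missing: ",
                paste(colnames(vals)[drop], collapse = ", ")))
    vals <- vals[, !drop, drop = FALSE]
    st <- st[, !drop, drop = FALSE]
  }
  for (m in colnames(vals)) {
    miss <- st[, m] == "missing"
    if (!any(miss)) next
    vals[miss, m] <- mean(vals[!miss, m])
    st[miss, m] <- "imputed_mean"
  }
  set_values(table, vals, st)
}

#' Z-normalise metabolite levels
#'
#' Standardises each metabolite over all samples (both groups pooled) to
#' mean 0 and unit standard deviation.
#'
#' @param table A [sample_table()] with no remaining missing entries.
#' @return The normalised `sample_table`.
#' @export
normalize_metabolites <- function(table) {
  vals <- metabolite_matrix(table)
  if (anyNA(vals)) abort("normalize_metabolites: missing entries remain; impute first")
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance metabolite(s): ",
                 paste(colnames(vals)[sds == 0], collapse = ", ")))
  }
  vals <- scale(vals)
  attr(vals, "scaled:center") <- NULL
  attr(vals, "scaled:scale") <- NULL
  set_values(table, vals)
}

#' Summarise the cohort covariates by group
#'
#' Per covariate: group means and standard deviations plus a Welch
#' two-sample t-test p-value for the group difference. Descriptive only.
#'
#' @param table A [sample_table()] with both groups present (size >= 2 each).
#' @return A tibble with one row per covariate: `covariate, mean_pre,
#'   sd_pre, mean_post, sd_post, p_value`, with group counts in attributes
#'   `n_pre`/`n_post`.
#' @export
summarize_cohort <- function(table) {
  n_pre <- sum(table$group == "pre")
  n_post <- sum(table$group == "post")
  if (n_pre < 2 || n_post < 2) {
    abort("both groups need at least 2 samples to summarise (SD undefined)")
  }
  out <- purrr::map_dfr(cohort_covariates(), function(cv) {
    x <- table[[cv]][table$group == "pre"]
    y <- table[[cv]][table$group == "post"]
    tibble(covariate = cv,
           mean_pre = mean(x), sd_pre = stats::sd(x),
           mean_post = mean(y), sd_post = stats::sd(y),
           p_value = stats::t.test(x, y)$p.value)
  })
  attr(out, "n_pre") <- n_pre
  attr(out, "n_post") <- n_post
  out
}

#' Run the full preprocessing chain
#'
#' Fixed order: measurability filter, half-minimum below-LOD imputation,
#' covariate residualisation, mean imputation of missing entries,
#' z-normalisation. A machine-readable report of what each stage did is
#' attached as attribute `"report"` (see [preprocess_report()]).
#'
#' @param table A raw [sample_table()].
#' @param min_fraction Measurability threshold for [filter_metabolites()].
#' @param covariates Covariates for [adjust_covariates()]; `NULL` skips
#'   adjustment.
#' @param max_missing Missingness bound for [impute_missing()].
#' @return The preprocessed `sample_table` (normalised residuals).
#' @export
preprocess <- function(table, min_fraction = 0.8,
                       covariates = cohort_covariates(),
                       max_missing = 0.05) {
  st0 <- status_matrix(table)
  filtered <- filter_metabolites(table, min_fraction)
  lod <- impute_below_lod(filtered)
  adj <- if (is.null(covariates)) lod else adjust_covariates(lod, covariates)
  imp <- withCallingHandlers(
    impute_missing(adj, max_missing),
    warning = function(w) invokeRestart("muffleWarning"))
  out <- normalize_metabolites(imp)
  report <- list(
    n_samples = nrow(table),
    n_metabolites_in = length(metabolites(table)),
    n_metabolites_out = length(metabolites(out)),
    dropped_low_measurability = attr(filtered, "dropped") %||% character(),
    dropped_high_missingness = setdiff(metabolites(adj), metabolites(imp)),
    n_below_lod_imputed = sum(st0 == "below_lod"),
    n_missing_imputed = sum(status_matrix(out) == "imputed_mean"),
    covariates = covariates %||% character(),
    pipeline = c("filter_metabolites", "impute_below_lod",
                 if (!is.null(covariates)) "adjust_covariates",
                 "impute_missing", "normalize_metabolites")
  )
  attr(out, "report") <- report
  out
}

#' Preprocessing report of a preprocessed table
#' @param table Output of [preprocess()].
#' @return Named list describing drops and imputations per stage.
#' @export
preprocess_report <- function(table) attr(table, "report")
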