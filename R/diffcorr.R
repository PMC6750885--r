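#' Fisher z-transformation
#'
#' `z = 0.5 * log((1 + r) / (1 - r))` = `atanh(r)`: variance-stabilises a
#' sample Pearson correlation (sampling variance approximately `1/(n-3)`).
#' An odd function of `r`. Perfect correlations are a domain error — no
#' silent clamping; callers must handle degenerate `|r| = 1` explicitly.
#'
#' @param r Correlation(s), each strictly inside (-1, 1).
#' @return The transform, vectorised over `r`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    abort("fisher_z is undefined for |r| >= 1")
  }
  atanh(r)
}

#' Differential correlation statistic
#'
#' The weighted difference of Fisher z-transformed per-group correlations:
#' `sqrt((n_pre - 3) / 2) * z_pre - sqrt((n_post - 3) / 2) * z_post`.
#' Each weighted term has variance 1/2 under independent sampling, so the
#' statistic is approximately standard normal under the no-difference null
#' for any pair of group sizes. Antisymmetric under swapping the groups
#' (together with their sizes).
#'
#' @param r_pre,r_post Per-group Pearson correlations of a metabolite pair.
#' @param n_pre,n_post Group sample sizes; both must exceed 3.
#' @param direction `"pre_minus_post"` (default, the order above) or
#'   `"post_minus_pre"` to flip the reporting sign.
#' @return The differential correlation, vectorised over the correlations.
#' @export
differential_correlation <- function(r_pre, r_post, n_pre, n_post,
                                     direction = c("pre_minus_post",
                                                   "post_minus_pre")) {
  direction <- match.arg(direction)
  if (n_pre <= 3 || n_post <= 3) abort("group sizes must exceed 3")
  d <- sqrt((n_pre - 3) / 2) * fisher_z(r_pre) -
    sqrt((n_post - 3) / 2) * fisher_z(r_post)
  if (direction == "post_minus_pre") -d else d
}

#' Within-group pairwise Pearson correlations
#'
#' Computes the full symmetric correlation matrix of one group's samples
#' together with two-sided Pearson-test p-values for every unordered pair
#' (for `m` metabolites, `m * (m - 1) / 2` pairs).
#'
#' @param table A preprocessed [sample_table()] (no missing values).
#' @param group `"pre"` or `"post"`.
#' @return A `group_correlation`: list with `group`, `n`, `r` (correlation
#'   matrix), `p` (p-value matrix). Use [corr_pairs()] for the tidy
#'   per-pair view.
#' @export
pairwise_correlations <- function(table, group) {
  group <- match.arg(group, c("pre", "post"))
  vals <- metabolite_matrix(table)[table$group == group, , drop = FALSE]
  n <- nrow(vals)
  if (n <= 3) abort(paste0("group '", group, "' has ", n, " samples; > 3 required"))
  if (anyNA(vals)) abort("missing values present; preprocess first")
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance metabolite(s) in group '", group, "': ",
                 paste(colnames(vals)[sds == 0], collapse = ", ")))
  }
  r <- stats::cor(vals)
  # two-sided test via the t transform, as in cor.test
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  diag(p) <- NA_real_
  structure(list(group = group, n = n, r = r, p = p),
            class = "group_correlation")
}

#' @export
print.group_correlation <- function(x, ...) {
  m <- ncol(x$r)
  cat(sprintf("# group_correlation: group '%s', n = %d, %d metabolites (%d pairs)\n",
              x$group, x$n, m, m * (m - 1) / 2))
  invisible(x)
}

#' Tidy per-pair view of a group correlation
#' @param corr A `group_correlation` from [pairwise_correlations()].
#' @return Tibble `met_i, met_j, r, p` with one row per unordered pair
#'   (`met_i < met_j` by name).
#' @export
corr_pairs <- function(corr) {
  mets <- colnames(corr$r)
  idx <- which(upper.tri(corr$r), arr.ind = TRUE)
  ord <- mets[idx[, 1]] < mets[idx[, 2]]
  tibble(met_i = ifelse(ord, mets[idx[, 1]], mets[idx[, 2]]),
         met_j = ifelse(ord, mets[idx[, 2]], mets[idx[, 1]]),
         r = corr$r[idx], p = corr$p[idx]) |>
    arrange(.data$met_i, .data$met_j)
}

#' Bonferroni-significant correlated pairs within a group
#'
#' Selects pairs whose raw Pearson p-value falls strictly below
#' `alpha / n_pairs`, where the divisor is the full pair count of the
#' matrix (family-wise error control over all pairs tested).
#'
#' @param corr A `group_correlation`.
#' @param alpha Family-wise level (default 0.05).
#' @return Tibble of selected pairs (`met_i, met_j, r, p`), with the
#'   per-test threshold in attribute `"threshold"`.
#' @export
significant_pairs <- function(corr, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  pairs <- corr_pairs(corr)
  thr <- alpha / nrow(pairs)
  out <- filter(pairs, .data$p < thr)
  attr(out, "threshold") <- thr
  out
}

#' Overlap fraction of two pair sets
#'
#' The fraction of pairs in the first set also present in the second:
#' `|pre & post| / |pre|`. Defined as 0 for an empty first set.
#'
#' @param pre_set,post_set Tibbles with columns `met_i, met_j` (unordered
#'   pairs, names ordered within each row).
#' @return A proportion in `[0, 1]`.
#' @export
overlap_fraction <- function(pre_set, post_set) {
  key <- function(s) paste(pmin(s$met_i, s$met_j), pmax(s$met_i, s$met_j))
  if (nrow(pre_set) == 0) {
    inform("overlap_fraction: first set is empty; returning 0")
    return(0)
  }
  mean(key(pre_set) %in% key(post_set))
}

# r_diff matrix for a split of the value matrix given row indices per group.
rdiff_matrix <- function(vals, pre_idx, post_idx, w_pre, w_post) {
  w_pre * atanh(stats::cor(vals[pre_idx, , drop = FALSE])) -
    w_post * atanh(stats::cor(vals[post_idx, , drop = FALSE]))
}

#' Permutation test of differential correlations
#'
#' For every unordered metabolite pair, computes the observed differential
#' correlation and a two-sided permutation p-value against `B` random
#' relabelings of the samples that preserve the two group sizes. One
#' shared set of permutations is used for all pairs, preserving the
#' cross-pair dependence structure. The add-one estimator
#' `p = (1 + #(|r_diff_b| >= |r_diff_obs|)) / (B + 1)` never returns 0;
#' its floor is `1 / (B + 1)`.
#'
#' Permutations relabel the preprocessed (residualised, normalised)
#' values; covariates are not re-adjusted inside the loop, since the
#' adjustment is group-blind.
#'
#' @param table A preprocessed [sample_table()].
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed for the permutation draws.
#' @param direction Sign convention passed to
#'   [differential_correlation()].
#' @param permutations Optional integer matrix (`B` rows, one permutation
#'   of `1:n` per row; the first `n_pre` entries of a row form the
#'   permuted pre group). Overrides `B`/`seed`; intended for oracle
#'   checks against an external reimplementation.
#' @return Tibble with one row per pair: `met_i, met_j, r_pre, r_post,
#'   z_pre, z_post, r_diff, p_perm, sign` (`sign` of `r_diff`:
#'   `"negative"`/`"positive"`).
#' @export
permutation_test <- function(table, B = 1000, seed = 1L,
                             direction = c("pre_minus_post",
                                           "post_minus_pre"),
                             permutations = NULL) {
  direction <- match.arg(direction)
  vals <- metabolite_matrix(table)
  if (anyNA(vals)) abort("missing values present; preprocess first")
  n <- nrow(vals)
  n_pre <- sum(table$group == "pre")
  n_post <- n - n_pre
  if (n_pre <= 3 || n_post <= 3) abort("both groups need > 3 samples")
  if (is.null(permutations)) {
    if (B < 1) abort("B must be at least 1")
    permutations <- local_seed(seed,
      t(replicate(B, sample.int(n))))
  } else {
    permutations <- as.matrix(permutations)
    stopifnot(ncol(permutations) == n)
    B <- nrow(permutations)
  }
  w_pre <- sqrt((n_pre - 3) / 2)
  w_post <- sqrt((n_post - 3) / 2)
  sgn <- if (direction == "post_minus_pre") -1 else 1

  pre_idx <- which(table$group == "pre")
  post_idx <- which(table$group == "post")
  r_pre_m <- stats::cor(vals[pre_idx, , drop = FALSE])
  r_post_m <- stats::cor(vals[post_idx, , drop = FALSE])
  obs <- sgn * (w_pre * atanh(r_pre_m) - w_post * atanh(r_post_m))

  ut <- upper.tri(obs)
  obs_v <- abs(obs[ut])
  exceed <- integer(length(obs_v))
  for (b in seq_len(B)) {
    pm <- permutations[b, ]
    rd <- rdiff_matrix(vals, pm[seq_len(n_pre)], pm[(n_pre + 1):n],
                       w_pre, w_post)
    exceed <- exceed + (abs(rd[ut]) >= obs_v)
  }
  p_perm <- (1 + exceed) / (B + 1)

  mets <- colnames(vals)
  idx <- which(ut, arr.ind = TRUE)
  ord <- mets[idx[, 1]] < mets[idx[, 2]]
  tibble(met_i = ifelse(ord, mets[idx[, 1]], mets[idx[, 2]]),
         met_j = ifelse(ord, mets[idx[, 2]], mets[idx[, 1]]),
         r_pre = r_pre_m[ut], r_post = r_post_m[ut],
         z_pre = atanh(r_pre_m[ut]), z_post = atanh(r_post_m[ut]),
         r_diff = obs[ut], p_perm = p_perm,
         sign = ifelse(obs[ut] < 0, "negative", "positive")) |>
    arrange(.data$met_i, .data$met_j)
}

#' Select differential edges at a permutation p-value threshold
#'
#' Keeps edges with `p_perm <= p_threshold` (inclusive), sorted by
#' `|r_diff|` descending with ties broken by metabolite names.
#'
#' @param edges Output of [permutation_test()].
#' @param p_threshold Threshold in (0, 1] (default 0.01).
#' @return The selected edge tibble.
#' @export
select_edges <- function(edges, p_threshold = 0.01) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  edges |>
    filter(.data$p_perm <= p_threshold) |>
    arrange(desc(abs(.data$r_diff)), .data$met_i, .data$met_j)
}

#' Write the per-pair differential correlation table to CSV
#' @param edges Output of [permutation_test()] or [select_edges()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  readr::write_csv(edges, path)
  invisible(path)
}
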