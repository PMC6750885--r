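groups_8 <- rep(c("pre", "post"), each = 4)

test_that("measurability filter keeps metabolites at the inclusive 80% boundary", {
  vals <- matrix(rnorm(100 * 3), 100,
                 dimnames = list(NULL, c("keep_all", "boundary", "drop_me")))
  st <- matrix("quantified", 100, 3,
               dimnames = list(NULL, colnames(vals)))
  st[1:20, "boundary"] <- "below_lod"   # measurable in exactly 80 of 100
  st[1:21, "drop_me"] <- "missing"      # measurable in 79 of 100
  vals[st != "quantified"] <- NA
  tab <- make_table(vals, rep(c("pre", "post"), 50))
  attr(tab, "status") <- st
  out <- suppressMessages(filter_metabolites(tab, 0.8))
  expect_setequal(metabolites(out), c("keep_all", "boundary"))
  expect_identical(attr(out, "dropped"), "drop_me")
  # identity when everything is measurable
  full <- make_table(matrix(rnorm(40), 10), rep(c("pre", "post"), 5))
  expect_equal(metabolite_matrix(filter_metabolites(full)),
               metabolite_matrix(full))
  # dropping everything is an error
  allbad <- tab
  attr(allbad, "status")[] <- "missing"
  expect_error(filter_metabolites(allbad), "threshold")
})

test_that("below-LOD entries become half the minimum quantified level", {
  vals <- matrix(c(0.4, 0.6, 1.0, NA, NA, 2, 3, 4, 5, 6), ncol = 2,
                 dimnames = list(NULL, c("m1", "m2")))
  st <- matrix("quantified", 5, 2, dimnames = list(NULL, c("m1", "m2")))
  st[4:5, "m1"] <- "below_lod"
  tab <- make_table(vals, rep(c("pre", "post"), c(3, 2)))
  attr(tab, "status") <- st
  out <- impute_below_lod(tab)
  expect_equal(unname(metabolite_matrix(out)[4:5, "m1"]), c(0.2, 0.2))
  expect_equal(unname(status_matrix(out)[4:5, "m1"]),
               rep("imputed_lod", 2))
  # no below-LOD entries: identity
  expect_equal(metabolite_matrix(impute_below_lod(out)),
               metabolite_matrix(out))
  # a metabolite entirely below LOD has no defined minimum
  st2 <- st; st2[, "m1"] <- "below_lod"
  tab2 <- make_table(vals, rep(c("pre", "post"), c(3, 2)))
  attr(tab2, "status") <- st2
  expect_error(impute_below_lod(tab2), "no quantified")
})

test_that("covariate residuals are exactly orthogonal to the covariates", {
  st <- generate_study(simulation_config(n_metabolites = 10, seed = 2,
                                         lod_quantile = 0,
                                         missing_rate = 0))
  out <- adjust_covariates(st$table)
  vals <- metabolite_matrix(out)
  for (cv in cohort_covariates()) {
    expect_lt(max(abs(cor(vals, out[[cv]]))), 1e-8)
  }
})

test_that("with zero generative covariate effects residuals track centred values", {
  st <- generate_study(simulation_config(
    n_pre = 1200, n_post = 1200, n_metabolites = 4, shared_blocks = list(),
    differential_pairs = NULL, lod_quantile = 0, missing_rate = 0,
    seed = 8))
  raw <- metabolite_matrix(st$table)
  res <- metabolite_matrix(adjust_covariates(st$table,
                                             c("bmi", "activity",
                                               "menarche_age")))
  centred <- scale(raw, scale = FALSE)
  # covariates carry no signal, so residualisation barely moves anything
  expect_gt(min(diag(cor(res, centred))), 0.995)
})

test_that("rank-deficient covariate designs are rejected", {
  vals <- matrix(rnorm(16), 8, dimnames = list(NULL, c("m1", "m2")))
  covs <- tibble::tibble(age = 1:8, bmi = 2 * (1:8), activity = rep(7, 8),
                         menarche_age = rep(13, 8))
  tab <- make_table(vals, groups_8, covs)
  expect_error(adjust_covariates(tab, c("age", "bmi")), "rank deficient")
})

test_that("mean imputation fills below the bound and drops at or above it", {
  vals <- matrix(rnorm(100 * 3), 100,
                 dimnames = list(NULL, c("ok", "light", "heavy")))
  st <- matrix("quantified", 100, 3, dimnames = list(NULL, colnames(vals)))
  st[1:3, "light"] <- "missing"   # 3% -> filled
  st[1:6, "heavy"] <- "missing"   # 6% -> dropped
  vals[st == "missing"] <- NA
  tab <- make_table(vals, rep(c("pre", "post"), 50))
  attr(tab, "status") <- st
  out <- suppressWarnings(impute_missing(tab))
  expect_setequal(metabolites(out), c("ok", "light"))
  expect_equal(unname(metabolite_matrix(out)[1:3, "light"]),
               rep(mean(vals[-(1:3), "light"]), 3))
  expect_warning(impute_missing(tab), "heavy")
  # identity with no missing entries
  clean <- make_table(matrix(rnorm(40), 10), rep(c("pre", "post"), 5))
  expect_equal(metabolite_matrix(impute_missing(clean)),
               metabolite_matrix(clean))
})

test_that("normalisation yields pooled mean 0 / SD 1 and is idempotent", {
  tab <- make_table(matrix(rexp(60) * 10, 12, 5),
                    rep(c("pre", "post"), each = 6))
  out <- normalize_metabolites(tab)
  vals <- metabolite_matrix(out)
  expect_lt(max(abs(colMeans(vals))), 1e-8)
  expect_lt(max(abs(apply(vals, 2, sd) - 1)), 1e-8)
  again <- normalize_metabolites(out)
  expect_lt(max(abs(metabolite_matrix(again) - vals)), 1e-8)
  # zero-variance column is an error naming the column
  bad <- make_table(cbind(flat = rep(1, 8), ok = rnorm(8)), groups_8)
  expect_error(normalize_metabolites(bad), "flat")
})

test_that("cohort summary reports group moments, counts and Welch p-values", {
  st <- generate_study(simulation_config(n_metabolites = 5, seed = 4))
  summ <- summarize_cohort(st$table)
  expect_equal(attr(summ, "n_pre"), 55)
  expect_equal(attr(summ, "n_post"), 64)
  age <- summ[summ$covariate == "age", ]
  expect_equal(age$mean_pre, 39.4, tolerance = 0.1)   # sampling error at n=55
  expect_equal(age$mean_post, 57.2, tolerance = 0.08)
  expect_lt(age$p_value, 1e-10)
  # identical groups: no mean shift detectable
  vals <- matrix(rnorm(20), 10, dimnames = list(NULL, c("a", "b")))
  covs <- tibble::tibble(age = rep(c(30, 40, 50, 35, 45), 2),
                         bmi = rep(c(22, 24, 26, 28, 30), 2),
                         activity = rep(c(6, 7, 8, 9, 10), 2),
                         menarche_age = rep(c(11, 12, 13, 14, 15), 2))
  tab <- make_table(vals, rep(c("pre", "post"), each = 5), covs)
  summ2 <- summarize_cohort(tab)
  expect_true(all(summ2$p_value > 1 - 1e-8))
  # undersized groups are rejected
  tiny <- make_table(matrix(rnorm(4), 2, dimnames = list(NULL, c("a", "b"))),
                     c("pre", "post"))
  expect_error(summarize_cohort(tiny), "at least 2")
})

test_that("the preprocessing chain is ordered, reported and stable on rerun", {
  st <- generate_study(simulation_config(n_metabolites = 20, seed = 6))
  out <- suppressMessages(preprocess(st$table))
  rep <- preprocess_report(out)
  expect_identical(rep$pipeline,
                   c("filter_metabolites", "impute_below_lod",
                     "adjust_covariates", "impute_missing",
                     "normalize_metabolites"))
  expect_equal(rep$n_metabolites_out, length(metabolites(out)))
  vals <- metabolite_matrix(out)
  expect_lt(max(abs(colMeans(vals))), 1e-8)
  # rerunning the chain on its own output only re-normalises (idempotent
  # within tolerance: values are already residual-orthogonal and scaled)
  again <- suppressMessages(preprocess(out))
  expect_lt(max(abs(metabolite_matrix(again) - vals)), 1e-6)
})

test_that("retained panel size is monotone non-increasing in min_fraction", {
  st <- generate_study(simulation_config(n_metabolites = 40,
                                         lod_quantile = 0.1,
                                         missing_rate = 0.04, seed = 12))
  sizes <- vapply(c(0.5, 0.85, 0.88, 0.95), function(f) {
    tryCatch(
      length(metabolites(suppressMessages(filter_metabolites(st$table, f)))),
      error = function(e) 0L)  # dropping every metabolite errors by contract
  }, 0L)
  expect_equal(sizes[1], 40L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("age-driven spurious correlation is removed by adjustment", {
  # Two independent metabolites that correlate only through a shared age
  # effect: before adjustment the pooled correlation is strong, after
  # residualisation it falls below the Bonferroni significance bound.
  hits <- vapply(1:5, function(s) {
    st <- generate_study(simulation_config(
      n_metabolites = 6, shared_blocks = list(), differential_pairs = NULL,
      covariate_effects = c(age = 0.08), lod_quantile = 0, missing_rate = 0,
      seed = s))
    pre <- suppressMessages(preprocess(st$table))
    raw_tab <- normalize_metabolites(impute_below_lod(st$table))
    n <- nrow(pre)
    r_raw <- cor(metabolite_matrix(raw_tab))[1, 2]
    r_adj <- cor(metabolite_matrix(pre))[1, 2]
    thr <- 0.05 / choose(6, 2)
    p_adj <- 2 * pt(-abs(r_adj) * sqrt((n - 2) / (1 - r_adj^2)), n - 2)
    c(abs(r_raw) > abs(r_adj), p_adj > thr)
  }, logical(2))
  expect_gte(mean(hits[2, ]), 0.8)   # adjusted correlation insignificant
  expect_gte(mean(hits[1, ]), 0.8)   # and smaller than the raw one
})
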