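test_that("fisher_z matches its closed form and rejects perfect correlation", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))   # odd function
  expect_error(fisher_z(1), "undefined")
  expect_error(fisher_z(-1), "undefined")
  expect_error(fisher_z(c(0.2, 1.0)), "undefined")
})

test_that("differential correlation evaluates its closed forms", {
  expect_equal(differential_correlation(0.8, 0.8, 55, 55), 0)
  expect_equal(differential_correlation(0.8, 0.8, 55, 64),
               atanh(0.8) * (sqrt(26) - sqrt(30.5)), tolerance = 1e-12)
  expect_equal(round(differential_correlation(0.8, 0.8, 55, 64), 4), -0.4654)
  expect_equal(differential_correlation(0.6, 0, 43, 43),
               sqrt(20) * atanh(0.6), tolerance = 1e-12)
  expect_equal(round(differential_correlation(0.6, 0, 43, 43), 4), 3.0998)
  expect_error(differential_correlation(0.5, 0.5, 3, 10), "exceed 3")
})

test_that("swapping groups (with their sizes) negates r_diff exactly", {
  set.seed(31)
  for (k in 1:25) {
    r1 <- runif(1, -0.95, 0.95); r2 <- runif(1, -0.95, 0.95)
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    expect_equal(differential_correlation(r1, r2, n1, n2),
                 -differential_correlation(r2, r1, n2, n1),
                 tolerance = 1e-12)
  }
  # the direction flag flips the reported sign
  expect_equal(differential_correlation(0.6, 0.1, 20, 30),
               -differential_correlation(0.6, 0.1, 20, 30,
                                         direction = "post_minus_pre"))
})

test_that("pair enumeration follows m(m-1)/2, including the panel sizes 167/168", {
  for (m in c(5, 167, 168)) {
    vals <- matrix(rnorm(10 * m), 10)
    tab <- make_table(vals, rep(c("pre", "post"), each = 5))
    gc <- pairwise_correlations(tab, "pre")
    expect_equal(nrow(corr_pairs(gc)), m * (m - 1) / 2)
  }
  # 167 metabolites give 13,861 unordered pairs; 168 give 14,028
  expect_equal(167 * 166 / 2, 13861)
  expect_equal(168 * 167 / 2, 14028)
})

test_that("pairwise correlations and p-values agree with cor.test", {
  set.seed(7)
  vals <- matrix(rnorm(12 * 4), 12, dimnames = list(NULL, letters[1:4]))
  tab <- make_table(vals, rep(c("pre", "post"), each = 6))
  gc <- pairwise_correlations(tab, "post")
  sub <- vals[7:12, ]
  for (i in 1:3) for (j in (i + 1):4) {
    ct <- cor.test(sub[, i], sub[, j])
    expect_equal(gc$r[i, j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(gc$p[i, j], ct$p.value, tolerance = 1e-12)
  }
  expect_equal(diag(gc$r), rep(1, 4), ignore_attr = TRUE)
  # degenerate group input is rejected
  flat <- vals; flat[7:12, 1] <- 5
  tabf <- make_table(flat, rep(c("pre", "post"), each = 6))
  expect_error(pairwise_correlations(tabf, "post"), "zero-variance")
  expect_error(pairwise_correlations(tab[1:3, ], "pre"), "> 3")
})

test_that("Bonferroni screening uses the full pair count and strict inequality", {
  gc <- structure(list(group = "pre", n = 10,
                       r = diag(3) * 0 + diag(3),
                       p = matrix(NA, 3, 3)), class = "group_correlation")
  colnames(gc$r) <- rownames(gc$r) <- c("a", "b", "c")
  colnames(gc$p) <- rownames(gc$p) <- c("a", "b", "c")
  gc$p[1, 2] <- gc$p[2, 1] <- 1e-9
  gc$p[1, 3] <- gc$p[3, 1] <- 0.05 / 3   # exactly at the boundary: excluded
  gc$p[2, 3] <- gc$p[3, 2] <- 0.9
  out <- significant_pairs(gc, 0.05)
  expect_equal(nrow(out), 1)
  expect_equal(out$met_i, "a"); expect_equal(out$met_j, "b")
  expect_equal(attr(out, "threshold"), 0.05 / 3)
  # monotone in alpha
  expect_lte(nrow(significant_pairs(gc, 0.025)), nrow(out))
  # all p = 1 selects nothing
  gc$p[upper.tri(gc$p)] <- 1; gc$p[lower.tri(gc$p)] <- 1
  expect_equal(nrow(significant_pairs(gc, 0.05)), 0)
})

test_that("overlap fraction counts shared pairs relative to the first set", {
  ab <- tibble::tibble(met_i = c("A", "A"), met_j = c("B", "C"))
  expect_equal(overlap_fraction(ab, ab), 1)
  expect_equal(overlap_fraction(
    ab, tibble::tibble(met_i = c("D", "E"), met_j = c("E", "F"))), 0)
  expect_equal(overlap_fraction(
    ab, tibble::tibble(met_i = c("A", "B"), met_j = c("B", "D"))), 0.5)
  expect_message(
    expect_equal(overlap_fraction(ab[0, ], ab), 0), "empty")
})

test_that("permutation p-values match a naive reimplementation exactly", {
  set.seed(99)
  vals <- matrix(rnorm(8 * 4), 8, dimnames = list(NULL, paste0("m", 1:4)))
  groups <- rep(c("pre", "post"), each = 4)
  perms <- t(replicate(10, sample.int(8)))
  tab <- make_table(vals, groups)
  got <- permutation_test(tab, permutations = perms)
  want <- naive_permutation_test(vals, groups, perms)
  merged <- dplyr::inner_join(got, want, by = c("met_i", "met_j"),
                              suffix = c("", "_naive"))
  expect_equal(nrow(merged), 6)
  expect_equal(merged$r_diff, merged$r_diff_naive, tolerance = 1e-12)
  expect_identical(merged$p_perm, merged$p_perm_naive)
})

test_that("permutation test is seed-reproducible with the add-one floor", {
  st <- generate_study(simulation_config(
    n_pre = 20, n_post = 22, n_metabolites = 6, shared_blocks = list(),
    differential_pairs = tibble::tibble(i = 1L, j = 2L, r_pre = 0.95,
                                        r_post = -0.5),
    lod_quantile = 0, missing_rate = 0, seed = 21))
  pre <- suppressMessages(preprocess(st$table))
  a <- permutation_test(pre, B = 199, seed = 5)
  b <- permutation_test(pre, B = 199, seed = 5)
  expect_identical(a, b)
  c <- permutation_test(pre, B = 199, seed = 6)
  expect_false(identical(a$p_perm, c$p_perm))
  expect_gte(min(a$p_perm), 1 / 200)   # add-one estimator floor
  # the extreme planted pair hits the floor
  top <- a[a$met_i == "met_001" & a$met_j == "met_002", ]
  expect_equal(top$p_perm, 1 / 200)
  expect_error(permutation_test(pre, B = 0), "at least 1")
})

test_that("edge selection is inclusive at the threshold and ranked by |r_diff|", {
  edges <- tibble::tibble(
    met_i = c("a", "a", "b", "a"), met_j = c("b", "c", "c", "d"),
    r_pre = 0, r_post = 0, z_pre = 0, z_post = 0,
    r_diff = c(-3.2, 1.4, 2.5, -1.4),
    p_perm = c(0.001, 0.01, 0.02, 0.0099),
    sign = c("negative", "positive", "positive", "negative"))
  out <- select_edges(edges, 0.01)
  expect_equal(nrow(out), 3)                    # 0.01 retained, 0.02 not
  expect_equal(out$r_diff, c(-3.2, 1.4, -1.4))  # |r_diff| desc, name ties
  expect_equal(nrow(select_edges(edges, 1.0)), 4)
  expect_equal(nrow(select_edges(edges, 1e-4)), 0)
})

test_that("r_diff is null-calibrated and p-values agree with the normal tail", {
  # independent metabolites, no group difference: r_diff ~ N(0,1)
  st <- generate_study(simulation_config(
    n_pre = 55, n_post = 64, n_metabolites = 40, shared_blocks = list(),
    differential_pairs = NULL, lod_quantile = 0, missing_rate = 0,
    seed = 33))
  pre <- suppressMessages(preprocess(st$table))
  res <- permutation_test(pre, B = 400, seed = 3)
  expect_lt(abs(mean(res$r_diff)), 0.1)
  expect_gt(sd(res$r_diff), 0.9)
  expect_lt(sd(res$r_diff), 1.1)
  approx_p <- 2 * pnorm(-abs(res$r_diff))
  expect_lt(median(abs(res$p_perm - approx_p)), 0.05)
})
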