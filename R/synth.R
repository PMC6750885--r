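#' Configuration for a simulated two-group metabolomics study
#'
#' Defines the generative conditions for [generate_study()]: group sizes
#' matching a pre-/post-menopause cohort, a Biocrates-style panel size,
#' shared "housekeeping" correlation blocks present in both groups,
#' planted group-specific (differentially correlated) pairs, covariate
#' effects, below-LOD censoring and random missingness.
#'
#' @param n_pre,n_post Samples per group. Defaults 55 and 64, the group
#'   sizes of a pre-/post-menopause plasma cohort. Both must exceed 3:
#'   Fisher-z weights use `n - 3`.
#' @param n_metabolites Panel size (default 168, the number of metabolites
#'   a p180-style kit typically quantifies in >= 80% of plasma samples).
#' @param shared_blocks List of `c(size, rho)` pairs: consecutive blocks of
#'   metabolites given within-block correlation `rho` in *both* groups,
#'   mimicking co-regulated lipid classes. Block sizes must sum to at most
#'   `n_metabolites`.
#' @param differential_pairs Data frame with columns `i`, `j` (metabolite
#'   indices) and `r_pre`, `r_post` (target latent correlations per group),
#'   the planted ground truth. Defaults to three strong differential pairs
#'   placed outside the shared blocks.
#' @param covariate_effects Named numeric vector of per-covariate slopes
#'   (latent log-scale units per covariate unit) applied to every
#'   metabolite. Default all zero; setting e.g. `age` non-zero plants
#'   age-driven confounding that covariate adjustment should remove.
#' @param lod_quantile Fraction of each metabolite's lowest concentrations
#'   censored as below-LOD (default 0.02).
#' @param missing_rate Fraction of quantified entries set missing at random
#'   (default 0.02; must stay below 0.05, the per-metabolite imputability
#'   bound used downstream).
#' @param seed Integer random seed; identical seeds give bit-identical
#'   studies.
#' @return A `simulation_config` list.
#' @seealso [generate_study()]
#' @export
simulation_config <- function(n_pre = 55,
                              n_post = 64,
                              n_metabolites = 168,
                              shared_blocks = default_shared_blocks(n_metabolites),
                              differential_pairs =
                                default_differential_pairs(n_metabolites),
                              covariate_effects = c(age = 0, bmi = 0,
                                                    activity = 0,
                                                    menarche_age = 0),
                              lod_quantile = 0.02,
                              missing_rate = 0.02,
                              seed = 1L) {
  if (n_pre <= 3 || n_post <= 3) {
    abort("n_pre and n_post must both exceed 3 (Fisher-z weights use n - 3)")
  }
  if (missing_rate >= 0.05) abort("missing_rate must be below 0.05")
  if (lod_quantile < 0 || lod_quantile >= 1) abort("lod_quantile must be in [0, 1)")
  dp <- as_tibble(differential_pairs %||% tibble(i = integer(), j = integer(),
                                                 r_pre = double(),
                                                 r_post = double()))
  if (nrow(dp) > 0) {
    stopifnot(all(c("i", "j", "r_pre", "r_post") %in% names(dp)))
    if (any(dp$i == dp$j)) abort("differential pairs must involve two distinct metabolites")
    if (any(abs(c(dp$r_pre, dp$r_post)) >= 1)) {
      abort("target correlations must lie strictly inside (-1, 1)")
    }
    if (any(dp$i > n_metabolites | dp$j > n_metabolites | dp$i < 1 | dp$j < 1)) {
      abort("differential pair indices must reference panel metabolites")
    }
  }
  blocks <- lapply(shared_blocks, function(b) {
    b <- unname(unlist(b))
    stopifnot(length(b) == 2, b[1] >= 2, abs(b[2]) < 1)
    list(size = as.integer(b[1]), rho = b[2])
  })
  if (sum(vapply(blocks, `[[`, 1L, "size")) > n_metabolites) {
    abort("shared block sizes must sum to at most n_metabolites")
  }
  ce <- c(age = 0, bmi = 0, activity = 0, menarche_age = 0)
  ce[names(covariate_effects)] <- covariate_effects
  structure(list(n_pre = as.integer(n_pre), n_post = as.integer(n_post),
                 n_metabolites = as.integer(n_metabolites),
                 shared_blocks = blocks, differential_pairs = dp,
                 covariate_effects = ce,
                 lod_quantile = lod_quantile, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_shared_blocks <- function(n_metabolites = 168) {
  # Co-regulated classes of a plasma panel: phosphatidylcholines,
  # sphingomyelins, acylcarnitines, amino acids. For small panels, keep
  # only the blocks that fit in at most half the panel.
  blocks <- list(c(12, 0.55), c(10, 0.45), c(8, 0.60), c(6, 0.50))
  sizes <- cumsum(vapply(blocks, `[`, 0, 1))
  blocks[sizes <= floor(n_metabolites / 2)]
}

#' @rdname simulation_config
#' @export
default_differential_pairs <- function(n_metabolites = 168) {
  # Placed just past the shared blocks; strong group contrasts of the kind
  # a differential network is built to find.
  start <- sum(vapply(default_shared_blocks(n_metabolites), `[`, 0, 1))
  full <- tibble(i = start + c(1L, 3L, 5L), j = start + c(2L, 4L, 6L),
                 r_pre = c(0.7, 0.8, -0.6), r_post = c(0.0, 0.1, 0.1))
  full[full$j <= n_metabolites, ]
}

# Assemble one group's target correlation matrix from blocks + planted
# pairs; repair to positive definite by eigenvalue clipping if needed.
assemble_correlation <- function(config, group) {
  m <- config$n_metabolites
  sigma <- diag(m)
  at <- 0
  for (b in config$shared_blocks) {
    idx <- (at + 1):(at + b$size)
    sigma[idx, idx] <- b$rho
    diag(sigma)[idx] <- 1
    at <- at + b$size
  }
  dp <- config$differential_pairs
  if (nrow(dp) > 0) {
    r <- if (group == "pre") dp$r_pre else dp$r_post
    for (k in seq_len(nrow(dp))) {
      sigma[dp$i[k], dp$j[k]] <- r[k]
      sigma[dp$j[k], dp$i[k]] <- r[k]
    }
  }
  repaired <- FALSE
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) <= 1e-8) {
    vals <- pmax(ev$values, 1e-6)
    sigma2 <- ev$vectors %*% (vals * t(ev$vectors))
    sigma2 <- stats::cov2cor(sigma2)
    if (max(abs(sigma2 - sigma)) > 0.05) {
      abort(paste0("target correlation structure for group '", group,
                   "' is not positive definite and cannot be repaired ",
                   "within tolerance; revisit block/pair targets"))
    }
    sigma <- sigma2
    repaired <- TRUE
  }
  list(sigma = sigma, repaired = repaired)
}

#' Generate a synthetic two-group metabolomics study
#'
#' Draws per-group latent log-concentrations from multivariate normals with
#' the configured correlation structure (shared housekeeping blocks in both
#' groups, planted differential pairs differing between groups), adds
#' covariate-driven shifts, exponentiates to positive concentrations (uM),
#' censors the lowest fraction of each metabolite as below-LOD and sets a
#' small fraction of entries missing. Age differs by group by design (the
#' pre-group is drawn around 39.4 +/- 9.1 years, the post-group around
#' 57.2 +/- 8.5), so a non-zero age effect creates genuine confounding;
#' the other covariates are group-invariant.
#'
#' Correlations are planted on the latent (log) scale; downstream analyses
#' z-normalise, so the latent structure is what the pipeline sees.
#'
#' @param config A [simulation_config()].
#' @return A `simulated_study`: list with `table` (a [sample_table()]),
#'   `truth` (tibble `met_i, met_j, r_pre, r_post` of planted pairs, by
#'   name with `met_i < met_j`), `config`, and `pd_repaired` (logical per
#'   group: was a positive-definiteness repair applied).
#' @examples
#' study <- generate_study(simulation_config(seed = 7))
#' study$truth
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  local_seed(config$seed, {
    m <- config$n_metabolites
    n_pre <- config$n_pre
    n_post <- config$n_post
    n <- n_pre + n_post
    met_names <- sprintf("met_%03d", seq_len(m))

    pre_struct <- assemble_correlation(config, "pre")
    post_struct <- assemble_correlation(config, "post")

    # Per-metabolite abundance scale: log-uniform over 0.1-100 uM with
    # moderate biological spread, fixed by the seed.
    mu <- stats::runif(m, log(0.1), log(100))
    sd_log <- stats::runif(m, 0.25, 0.6)

    draw_group <- function(n_g, sigma) {
      z <- matrix(stats::rnorm(n_g * m), n_g, m)
      z %*% chol(sigma)
    }
    z_pre <- draw_group(n_pre, pre_struct$sigma)
    z_post <- draw_group(n_post, post_struct$sigma)

    covs <- tibble(
      group = rep(c("pre", "post"), c(n_pre, n_post)),
      age = c(stats::rnorm(n_pre, 39.4, 9.1), stats::rnorm(n_post, 57.2, 8.5)),
      bmi = stats::rnorm(n, 29.2, 5.6),
      activity = stats::rnorm(n, 7.8, 1.6),
      menarche_age = stats::rnorm(n, 12.8, 1.8)
    )

    z <- rbind(z_pre, z_post)
    beta <- config$covariate_effects
    for (cv in names(beta)) {
      if (beta[[cv]] != 0) {
        shift <- beta[[cv]] * (covs[[cv]] - mean(covs[[cv]]))
        z <- z + shift  # same slope on every metabolite's latent scale
      }
    }

    conc <- exp(sweep(sweep(z, 2, sd_log, `*`), 2, mu, `+`))
    colnames(conc) <- met_names

    status <- matrix("quantified", n, m, dimnames = list(NULL, met_names))
    k_lod <- floor(config$lod_quantile * n)
    if (k_lod > 0) {
      for (jm in seq_len(m)) {
        cut <- order(conc[, jm])[seq_len(k_lod)]
        status[cut, jm] <- "below_lod"
      }
    }
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
      miss[status != "quantified"] <- FALSE
      status[miss] <- "missing"
    }
    conc[status != "quantified"] <- NA_real_

    tbl <- sample_table(
      bind_cols(tibble(sample_id = sprintf("S%03d", seq_len(n)),
                       group = covs$group),
                covs[c("age", "bmi", "activity", "menarche_age")],
                as_tibble(conc)),
      status = status
    )

    dp <- config$differential_pairs
    truth <- if (nrow(dp) > 0) {
      tibble(met_i = met_names[pmin(dp$i, dp$j)],
             met_j = met_names[pmax(dp$i, dp$j)],
             r_pre = dp$r_pre, r_post = dp$r_post)
    } else {
      tibble(met_i = character(), met_j = character(),
             r_pre = double(), r_post = double())
    }

    structure(list(table = tbl, truth = truth, config = config,
                   pd_repaired = c(pre = pre_struct$repaired,
                                   post = post_struct$repaired)),
              class = "simulated_study")
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("# A simulated_study: %d + %d samples, %d metabolites, %d planted pair(s)\n",
              x$config$n_pre, x$config$n_post, x$config$n_metabolites,
              nrow(x$truth)))
  invisible(x)
}

#' Write the planted ground truth of a simulated study to CSV
#' @param study A `simulated_study`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(study, path) {
  readr::write_csv(study$truth, path)
  invisible(path)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Recognised fields mirror the arguments of [simulation_config()];
#' `shared_blocks` is a list of `[size, rho]` pairs and
#' `differential_pairs` a list of `[i, j, r_pre, r_post]` records.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file path.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  dp <- raw$differential_pairs
  if (!is.null(dp)) {
    dp <- as_tibble(as.data.frame(do.call(rbind, lapply(dp, unlist))))
    names(dp) <- c("i", "j", "r_pre", "r_post")
    dp$i <- as.integer(dp$i); dp$j <- as.integer(dp$j)
  }
  args <- raw[intersect(names(raw),
                        c("n_pre", "n_post", "n_metabolites", "shared_blocks",
                          "covariate_effects", "lod_quantile", "missing_rate",
                          "seed"))]
  if (!is.null(args$covariate_effects)) {
    args$covariate_effects <- unlist(args$covariate_effects)
  }
  if (!is.null(dp)) args$differential_pairs <- dp
  do.call(simulation_config, args)
}
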