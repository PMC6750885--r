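#' Configuration for the end-to-end pipeline
#'
#' Bundles the input source (a CSV path or a [simulation_config()]), the
#' analysis thresholds and the permutation plan. All randomness flows from
#' the seeds recorded here, so identical configurations give byte-identical
#' reports.
#'
#' @param input Path to a sample-table CSV, or a `simulation_config` to
#'   generate one.
#' @param min_fraction Measurability threshold (default 0.8).
#' @param corr_alpha Family-wise level for within-group correlation
#'   screening (default 0.05).
#' @param edge_p Permutation p-value threshold for network edges
#'   (default 0.01).
#' @param screen_alpha Family-wise level for the VIP/univariate screen
#'   (default 0.05).
#' @param vip_cut VIP cut for the screen display (default 1).
#' @param B Number of permutations (default 1000).
#' @param seed Root seed for the permutation test and cross-validation.
#' @param direction Sign convention for [differential_correlation()].
#' @param n_orth Orthogonal components for the OPLS-DA stage.
#' @param top_k Hubs to report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, min_fraction = 0.8, corr_alpha = 0.05,
                            edge_p = 0.01, screen_alpha = 0.05,
                            vip_cut = 1, B = 1000, seed = 1L,
                            direction = "pre_minus_post", n_orth = 1,
                            top_k = 10) {
  stopifnot(min_fraction > 0, min_fraction <= 1,
            corr_alpha > 0, corr_alpha < 1,
            edge_p > 0, edge_p <= 1,
            screen_alpha > 0, screen_alpha < 1,
            B >= 1)
  structure(list(input = input, min_fraction = min_fraction,
                 corr_alpha = corr_alpha, edge_p = edge_p,
                 screen_alpha = screen_alpha, vip_cut = vip_cut,
                 B = as.integer(B), seed = as.integer(seed),
                 direction = direction, n_orth = n_orth, top_k = top_k),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level fields mirror [pipeline_config()]; an `input:` field holds a
#' CSV path, or a `simulate:` block holds [read_simulation_config()]
#' fields.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  input <- if (!is.null(raw$simulate)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(raw$simulate, tmp, auto_unbox = TRUE)
    read_simulation_config(tmp)
  } else if (!is.null(raw$input)) {
    raw$input
  } else {
    abort("pipeline config needs either `input:` (CSV path) or `simulate:`")
  }
  args <- raw[intersect(names(raw), setdiff(names(formals(pipeline_config)),
                                            "input"))]
  do.call(pipeline_config, c(list(input = input), args))
}

#' Run the full differential correlation pipeline
#'
#' Stages, in fixed order: load or simulate the sample table; preprocess
#' (filter, LOD-impute, covariate-adjust, mean-impute, normalise);
#' within-group correlation screening and overlap; differential
#' correlation permutation test and edge selection; network construction
#' and topology analysis; OPLS-DA with Q2, VIP/univariate screening and
#' covariate-adjusted association of the screened candidates.
#'
#' All stage outputs are written under `output_dir` (sample table, truth
#' if simulated, per-pair results CSV, GraphML network, screen CSV) plus
#' a top-level `report.json`. Identical config and seed give
#' byte-identical reports.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for stage outputs; created if needed.
#'   `NULL` skips all file output.
#' @return Invisibly, a list with every stage result (`table`,
#'   `preprocessed`, `corr_pre`, `corr_post`, `edges`, `selected`, `net`,
#'   `oplsda`, `q2`, `screen`, `association`, `report`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  out_path <- function(f) file.path(output_dir, f)

  truth <- NULL
  if (inherits(config$input, "simulation_config")) {
    study <- generate_study(config$input)
    table <- study$table
    truth <- study$truth
  } else {
    if (!file.exists(config$input)) {
      abort(paste0("input file not found: ", config$input))
    }
    table <- read_sample_table(config$input)
  }

  pre <- suppressMessages(preprocess(table, min_fraction = config$min_fraction))

  corr_pre <- pairwise_correlations(pre, "pre")
  corr_post <- pairwise_correlations(pre, "post")
  sig_pre <- significant_pairs(corr_pre, config$corr_alpha)
  sig_post <- significant_pairs(corr_post, config$corr_alpha)
  overlap <- if (nrow(sig_pre) > 0) overlap_fraction(sig_pre, sig_post) else 0

  edges <- permutation_test(pre, B = config$B, seed = config$seed,
                            direction = config$direction)
  selected <- select_edges(edges, config$edge_p)
  net <- build_network(selected)
  net_rep <- network_report(net, top_k = config$top_k)

  model <- fit_oplsda(pre, n_orth = config$n_orth)
  q2 <- cross_validated_q2(pre, seed = config$seed, n_orth = config$n_orth)
  screen <- screen_metabolites(pre, model = model,
                               alpha = config$screen_alpha)
  candidates <- screen$metabolite[screen$pass]
  adjusted <- suppressMessages(
    impute_missing(adjust_covariates(impute_below_lod(
      filter_metabolites(table, config$min_fraction)))))
  assoc <- if (length(candidates) > 0) {
    associate(adjusted, candidates)
  } else {
    tibble(metabolite = character(), estimate = double(),
           p_value = double())
  }

  report <- list(
    thresholds = config[c("min_fraction", "corr_alpha", "edge_p",
                          "screen_alpha", "vip_cut", "B", "seed",
                          "direction", "n_orth")],
    preprocessing = preprocess_report(pre),
    n_pairs_tested = nrow(edges),
    n_significant_pre = nrow(sig_pre),
    n_significant_post = nrow(sig_post),
    overlap_fraction = overlap,
    n_edges_selected = nrow(selected),
    network = net_rep[c("n_nodes", "n_edges", "mean_degree",
                        "component_sizes")],
    oplsda = list(R2X = model$R2X, R2Y = model$R2Y, Q2 = q2,
                  n_orth = config$n_orth),
    screen = list(threshold = attr(screen, "threshold"),
                  threshold_display = attr(screen, "threshold_display"),
                  n_pass = sum(screen$pass),
                  candidates = candidates),
    n_associated = sum(assoc$p_value < 0.05)
  )

  if (!is.null(output_dir)) {
    write_sample_table(table, out_path("sample_table.csv"))
    if (!is.null(truth)) readr::write_csv(truth, out_path("truth.csv"))
    write_edges(edges, out_path("differential_pairs.csv"))
    write_edges(selected, out_path("selected_edges.csv"))
    export_network(net, out_path("network.graphml"), "graphml")
    readr::write_csv(screen, out_path("screen.csv"))
    readr::write_csv(assoc, out_path("association.csv"))
    hub_tbl <- net_rep$hubs
    if (is.data.frame(hub_tbl)) {
      readr::write_csv(hub_tbl, out_path("hubs.csv"))
    }
    jsonlite::write_json(report, out_path("report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(table = table, truth = truth, preprocessed = pre,
                 corr_pre = corr_pre, corr_post = corr_post,
                 sig_pre = sig_pre, sig_post = sig_post,
                 edges = edges, selected = selected, net = net,
                 oplsda = model, q2 = q2, screen = screen,
                 association = assoc, report = report))
}
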