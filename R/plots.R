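#' @importFrom ggplot2 ggplot aes geom_point geom_hline geom_vline labs
#'   theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Score plot of an OPLS-DA fit
#'
#' Predictive score against the first orthogonal score (or sample index
#' when the model has no orthogonal component), coloured by class.
#'
#' @param object An `oplsda` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.oplsda <- function(object, ...) {
  cls <- ifelse(object$y_centered > 0, object$y_levels[2], object$y_levels[1])
  df <- tibble(
    predictive = object$scores,
    orthogonal = if (object$n_orth > 0) object$orth_scores[, 1]
                 else seq_along(object$scores),
    group = cls)
  ggplot(df, aes(.data$predictive, .data$orthogonal, colour = .data$group)) +
    geom_point(size = 2) +
    labs(x = "predictive score (t)",
         y = if (object$n_orth > 0) "orthogonal score (t_o)" else "sample index",
         colour = NULL, title = "OPLS-DA scores") +
    theme_minimal()
}

#' S-plot of an OPLS-DA fit
#'
#' Covariance vs correlation of each metabolite with the predictive score;
#' markers passing a VIP cut are highlighted.
#'
#' @param model An `oplsda` fit.
#' @param vip_cut Highlight metabolites with VIP above this value
#'   (default 1).
#' @return A ggplot.
#' @export
plot_splot <- function(model, vip_cut = 1) {
  df <- model$splot |>
    mutate(important = model$vip[.data$metabolite] > vip_cut)
  ggplot(df, aes(.data$covariance, .data$correlation,
                 colour = .data$important)) +
    geom_point() +
    geom_hline(yintercept = 0, linetype = 3) +
    geom_vline(xintercept = 0, linetype = 3) +
    labs(x = "cov(x, t)", y = "cor(x, t)",
         colour = paste0("VIP > ", vip_cut), title = "S-plot") +
    theme_minimal()
}

#' Degree distribution of a differential network
#'
#' @param net A graph from [build_network()].
#' @return A ggplot bar chart of node degrees.
#' @export
plot_degree_distribution <- function(net) {
  df <- centrality_scores(net) |> count(.data$degree)
  ggplot(df, aes(.data$degree, .data$n)) +
    ggplot2::geom_col() +
    labs(x = "node degree", y = "number of nodes",
         title = "Differential network degree distribution") +
    theme_minimal()
}

#' Volcano-style overview of differential correlations
#'
#' Plots every metabolite pair's differential correlation against its
#' permutation p-value (-log10 scale), marking the selection threshold.
#'
#' @param edges Output of [permutation_test()].
#' @param p_threshold Edge-selection threshold to mark (default 0.01).
#' @return A ggplot.
#' @export
plot_differential_pairs <- function(edges, p_threshold = 0.01) {
  ggplot(edges, aes(.data$r_diff, -log10(.data$p_perm))) +
    geom_point(alpha = 0.4) +
    geom_hline(yintercept = -log10(p_threshold), linetype = 2) +
    labs(x = "differential correlation r_diff",
         y = "-log10 permutation p",
         title = "Differential correlations") +
    theme_minimal()
}
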