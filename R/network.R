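#' Build a differential correlation network
#'
#' Constructs an undirected simple graph whose nodes are the metabolites
#' incident to at least one selected differential edge; edges carry the
#' differential correlation `r_diff`, its `sign`, the permutation p-value
#' and `weight = |r_diff|`.
#'
#' @param edges Edge tibble from [select_edges()] (columns `met_i, met_j,
#'   r_diff, p_perm, sign`); unordered pairs must be unique.
#' @return An [igraph::igraph] graph.
#' @export
build_network <- function(edges) {
  if (nrow(edges) == 0) return(igraph::make_empty_graph(0, directed = FALSE))
  key <- paste(pmin(edges$met_i, edges$met_j), pmax(edges$met_i, edges$met_j))
  if (anyDuplicated(key)) {
    abort("duplicate metabolite pair(s) in edge list; upstream contract violated")
  }
  if (any(edges$met_i == edges$met_j)) abort("self-loop edge in edge list")
  igraph::graph_from_data_frame(
    tibble(from = edges$met_i, to = edges$met_j,
           r_diff = edges$r_diff, sign = edges$sign,
           p_perm = edges$p_perm, weight = abs(edges$r_diff)),
    directed = FALSE)
}

#' Node centralities of a differential network
#'
#' Degree (raw count), shortest-path betweenness and classical closeness,
#' all on the unweighted topology. Connected components are handled
#' separately: betweenness excludes endpoints and is normalised by
#' `(N_c - 1) * (N_c - 2) / 2` within each component of size `N_c`;
#' closeness is `(N_c - 1) / sum(distances)` within the component.
#' Isolated conventions: a 2-node component has betweenness 0 and
#' closeness 1 for both nodes.
#'
#' @param net A graph from [build_network()].
#' @return Tibble `node, degree, betweenness, closeness`, one row per node.
#' @export
centrality_scores <- function(net) {
  if (igraph::vcount(net) == 0) {
    return(tibble(node = character(), degree = double(),
                  betweenness = double(), closeness = double()))
  }
  comp <- igraph::components(net)
  res <- purrr::map_dfr(seq_len(comp$no), function(ci) {
    sub <- igraph::induced_subgraph(net, which(comp$membership == ci))
    nc <- igraph::vcount(sub)
    # weights = NA: centralities are defined on the unweighted topology;
    # |r_diff| stays an edge attribute only
    btw <- igraph::betweenness(sub, directed = FALSE, weights = NA)
    if (nc > 2) btw <- btw / ((nc - 1) * (nc - 2) / 2)
    cls <- if (nc == 1) 0 else {
      igraph::closeness(sub, normalized = TRUE, weights = NA)
    }
    tibble(node = igraph::V(sub)$name,
           betweenness = unname(btw), closeness = unname(cls))
  })
  deg <- igraph::degree(net)
  res$degree <- unname(deg[res$node])
  res |>
    select("node", "degree", "betweenness", "closeness") |>
    arrange(.data$node)
}

#' Mean node degree
#' @param net A graph from [build_network()].
#' @return `2 * E / N`.
#' @export
mean_degree <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0) abort("mean degree of an empty network is undefined")
  2 * igraph::ecount(net) / n
}

#' Rank hub metabolites and flag bottlenecks
#'
#' Hubs are ranked by degree, ties broken by betweenness then node name.
#' Bottlenecks are nodes in the top `1 - bottleneck_quantile` fraction
#' (default: top decile) of either betweenness or closeness.
#'
#' @param net A graph from [build_network()].
#' @param top_k Number of top-ranked nodes to return; truncated with a
#'   warning if larger than the node count.
#' @param bottleneck_quantile Quantile defining the bottleneck cut
#'   (default 0.9).
#' @return Tibble `node, degree, betweenness, closeness, bottleneck`
#'   with the `top_k` highest-ranked nodes.
#' @export
identify_hubs <- function(net, top_k = 10, bottleneck_quantile = 0.9) {
  stopifnot(top_k >= 1)
  scores <- centrality_scores(net)
  if (nrow(scores) == 0) abort("cannot rank hubs of an empty network")
  if (top_k > nrow(scores)) {
    warn(paste0("top_k = ", top_k, " exceeds node count ", nrow(scores),
                "; truncating"))
    top_k <- nrow(scores)
  }
  b_cut <- stats::quantile(scores$betweenness, bottleneck_quantile,
                           names = FALSE)
  c_cut <- stats::quantile(scores$closeness, bottleneck_quantile,
                           names = FALSE)
  scores |>
    mutate(bottleneck = .data$betweenness >= b_cut | .data$closeness >= c_cut) |>
    arrange(desc(.data$degree), desc(.data$betweenness), .data$node) |>
    slice_head(n = top_k)
}

#' Export a differential network
#'
#' Writes GraphML (via igraph) or an edge-list CSV (`met_i, met_j, r_diff,
#' sign, p_perm, weight`). Round-trip safe with [import_network()].
#'
#' @param net A graph from [build_network()].
#' @param path Output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    df <- if (igraph::ecount(net) == 0) {
      tibble(met_i = character(), met_j = character(), r_diff = double(),
             sign = character(), p_perm = double(), weight = double())
    } else {
      el <- igraph::as_data_frame(net, what = "edges")
      tibble(met_i = pmin(el$from, el$to), met_j = pmax(el$from, el$to),
             r_diff = el$r_diff, sign = el$sign, p_perm = el$p_perm,
             weight = el$weight)
    }
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(
      met_i = "c", met_j = "c", r_diff = "d", sign = "c",
      p_perm = "d", weight = "d"))
    build_network(df)
  }
}

#' Topology report of a differential network
#'
#' @param net A graph from [build_network()].
#' @param top_k Hubs to list.
#' @return Named list: node/edge counts, mean degree, component sizes and
#'   the top hubs/bottlenecks; suitable for JSON serialisation.
#' @export
network_report <- function(net, top_k = 10) {
  if (igraph::vcount(net) == 0) {
    return(list(n_nodes = 0, n_edges = 0, mean_degree = NA,
                component_sizes = integer(), hubs = list()))
  }
  comp <- igraph::components(net)
  hubs <- identify_hubs(net, top_k = min(top_k, igraph::vcount(net)))
  list(n_nodes = igraph::vcount(net),
       n_edges = igraph::ecount(net),
       mean_degree = mean_degree(net),
       component_sizes = sort(unname(comp$csize), decreasing = TRUE),
       hubs = hubs)
}
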