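# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately naive and separate from the package's
# implementation paths.

# Build a sample_table from a bare value matrix and group labels, with
# covariates that carry no information unless supplied.
make_table <- function(values, groups, covariates = NULL) {
  n <- nrow(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("met_%03d", seq_len(ncol(values)))
  }
  covs <- covariates %||% tibble::tibble(
    age = 30 + seq_len(n), bmi = 25 + (seq_len(n) %% 3),
    activity = 7 + (seq_len(n) %% 2),
    menarche_age = 12 + (seq_len(n) %% 4) / 2)
  sample_table(dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%03d", seq_len(n)), group = groups),
    covs, tibble::as_tibble(values)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-rolled Pearson correlation (no stats::cor), for oracle use.
naive_cor <- function(x, y) {
  xm <- x - sum(x) / length(x)
  ym <- y - sum(y) / length(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# Naive differential-correlation permutation test: loops over pairs and
# permutations, recomputing everything from first principles.
naive_permutation_test <- function(values, groups, permutations) {
  n_pre <- sum(groups == "pre")
  n <- length(groups)
  w_pre <- sqrt((n_pre - 3) / 2)
  w_post <- sqrt((n - n_pre - 3) / 2)
  rdiff_one <- function(vals, pre_rows, i, j) {
    rp <- naive_cor(vals[pre_rows, i], vals[pre_rows, j])
    rq <- naive_cor(vals[-pre_rows, i], vals[-pre_rows, j])
    w_pre * 0.5 * log((1 + rp) / (1 - rp)) -
      w_post * 0.5 * log((1 + rq) / (1 - rq))
  }
  m <- ncol(values)
  out <- list()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      obs <- rdiff_one(values, which(groups == "pre"), i, j)
      count <- 0
      for (b in seq_len(nrow(permutations))) {
        perm <- permutations[b, ]
        permuted <- values[perm, , drop = FALSE]
        rd <- rdiff_one(permuted, seq_len(n_pre), i, j)
        if (abs(rd) >= abs(obs)) count <- count + 1
      }
      out[[length(out) + 1]] <- tibble::tibble(
        met_i = colnames(values)[i], met_j = colnames(values)[j],
        r_diff = obs, p_perm = (1 + count) / (nrow(permutations) + 1))
    }
  }
  dplyr::bind_rows(out)
}

# Brute-force centralities from an edge data frame (from, to):
# all-pairs shortest paths + path counts via BFS per source, classical
# component-wise normalisation.
brute_centralities <- function(edge_df, nodes = NULL) {
  nodes <- nodes %||% sort(unique(c(edge_df$from, edge_df$to)))
  nn <- length(nodes)
  adj <- matrix(FALSE, nn, nn, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edge_df))) {
    adj[edge_df$from[k], edge_df$to[k]] <- TRUE
    adj[edge_df$to[k], edge_df$from[k]] <- TRUE
  }
  dist <- matrix(Inf, nn, nn)
  nsp <- matrix(0, nn, nn)  # number of shortest paths
  for (s in seq_len(nn)) {
    dist[s, s] <- 0; nsp[s, s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer()
      for (u in frontier) {
        for (v in which(adj[u, ])) {
          if (is.infinite(dist[s, v])) {
            dist[s, v] <- dist[s, u] + 1
            nxt <- c(nxt, v)
          }
          if (dist[s, v] == dist[s, u] + 1) nsp[s, v] <- nsp[s, v] + nsp[s, u]
        }
      }
      frontier <- unique(nxt)
    }
  }
  btw <- numeric(nn)
  for (v in seq_len(nn)) {
    for (s in seq_len(nn - 1)) {
      for (t in (s + 1):nn) {
        if (s == v || t == v || is.infinite(dist[s, t])) next
        if (dist[s, v] + dist[v, t] == dist[s, t]) {
          btw[v] <- btw[v] + nsp[s, v] * nsp[v, t] / nsp[s, t]
        }
      }
    }
  }
  comp_size <- vapply(seq_len(nn), function(v) sum(is.finite(dist[v, ])), 0)
  btw_norm <- ifelse(comp_size > 2,
                     btw / ((comp_size - 1) * (comp_size - 2) / 2), 0)
  cls <- vapply(seq_len(nn), function(v) {
    d <- dist[v, is.finite(dist[v, ])]
    if (comp_size[v] == 1) 0 else (comp_size[v] - 1) / sum(d)
  }, 0)
  tibble::tibble(node = nodes, degree = rowSums(adj),
                 betweenness = btw_norm, closeness = cls)
}

# Direct one-component PLS (class response), the n_orth = 0 equivalence
# oracle for the OPLS-DA fit.
direct_pls1 <- function(X, y_centered) {
  w <- drop(crossprod(X, y_centered))
  w <- w / sqrt(sum(w^2))
  t <- drop(X %*% w)
  list(w = w, t = t, q = sum(y_centered * t) / sum(t^2))
}

# Standardise columns (oracle-side z-scoring).
zscale <- function(X) scale(X)[, , drop = FALSE]
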