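# Resolve (X, y) from either a sample_table or an explicit matrix + labels.
resolve_xy <- function(x, y = NULL) {
  if (inherits(x, "sample_table")) {
    list(X = metabolite_matrix(x), y = x$group)
  } else {
    if (is.null(y)) abort("y (group labels) required when x is a matrix")
    list(X = as.matrix(x), y = y)
  }
}

encode_class <- function(y) {
  lv <- sort(unique(as.character(y)))
  if (length(lv) != 2) abort("exactly two classes required")
  # pre/post cohorts order naturally as pre = -1, post = +1
  if (setequal(lv, c("pre", "post"))) lv <- c("pre", "post")
  yn <- ifelse(as.character(y) == lv[2], 1, -1)
  list(y = yn - mean(yn), levels = lv)
}

# Core orthogonal-projection NIPALS fit on centred/scaled X and centred y.
# Deterministic: single predictive component, fixed deflation order.
opls_core <- function(X, yc, n_orth) {
  m <- ncol(X)
  W_o <- matrix(0, m, 0); P_o <- matrix(0, m, 0)
  T_o <- matrix(0, nrow(X), 0)
  Xd <- X
  for (k in seq_len(n_orth)) {
    w <- drop(crossprod(Xd, yc)); w <- w / sqrt(sum(w^2))
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    w_o <- p - drop(crossprod(w, p)) * w
    no <- sqrt(sum(w_o^2))
    if (no < 1e-12) {
      abort("n_orth too large: no class-orthogonal variation left to extract")
    }
    w_o <- w_o / no
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
  }
  w <- drop(crossprod(Xd, yc)); w <- w / sqrt(sum(w^2))
  t <- drop(Xd %*% w)
  p <- drop(crossprod(Xd, t)) / sum(t^2)
  q <- sum(yc * t) / sum(t^2)
  list(w = w, t = t, p = p, q = q, W_o = W_o, P_o = P_o, T_o = T_o, Xd = Xd)
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis with
#' one predictive component and `n_orth` orthogonal components, fitted by
#' the NIPALS orthogonal-projection algorithm: class-orthogonal variation
#' is deflated from `X` first, then a single PLS component is fitted on
#' the deflated matrix. With `n_orth = 0` the fit reduces exactly to a
#' one-component PLS-DA.
#'
#' The fit is deterministic (no randomness, fixed deflation order).
#' VIP scores on the predictive component satisfy `mean(VIP^2) = 1`.
#'
#' @param x A preprocessed [sample_table()] (normalised), or a numeric
#'   matrix of column-standardised values.
#' @param y Group labels (two classes); taken from the table when `x` is a
#'   `sample_table`.
#' @param n_orth Number of orthogonal components (default 1).
#' @return An `oplsda` object: scores/loadings/weights for the predictive
#'   and orthogonal parts, `R2X`, `R2Y`, `vip`, and S-plot coordinates.
#' @export
fit_oplsda <- function(x, y = NULL, n_orth = 1) {
  xy <- resolve_xy(x, y)
  X <- xy$X
  if (anyNA(X)) abort("missing values present; preprocess first")
  enc <- encode_class(xy$y)
  if (nrow(X) < n_orth + 2) abort("too few samples for the requested n_orth")
  fit <- opls_core(X, enc$y, n_orth)

  ssx <- sum(X^2)
  ssx_pred <- sum(fit$t^2) * sum(fit$p^2)
  ssx_orth <- if (ncol(fit$T_o) > 0) {
    sum(vapply(seq_len(ncol(fit$T_o)), function(k)
      sum(fit$T_o[, k]^2) * sum(fit$P_o[, k]^2), 0))
  } else 0
  y_hat <- fit$t * fit$q
  r2y <- 1 - sum((enc$y - y_hat)^2) / sum(enc$y^2)

  m <- ncol(X)
  vip <- sqrt(m) * abs(fit$w)  # single component: VIP reduces to sqrt(m)|w|
  names(vip) <- colnames(X)

  s_cov <- drop(crossprod(X, fit$t)) / (length(fit$t) - 1)
  s_cor <- s_cov / (apply(X, 2, stats::sd) * stats::sd(fit$t))
  splot <- tibble(metabolite = colnames(X), covariance = unname(s_cov),
                  correlation = unname(s_cor))

  structure(list(
    weights = stats::setNames(fit$w, colnames(X)),
    scores = fit$t, loadings = stats::setNames(fit$p, colnames(X)),
    q = fit$q,
    orth_weights = fit$W_o, orth_loadings = fit$P_o, orth_scores = fit$T_o,
    n_orth = n_orth, y_levels = enc$levels, y_centered = enc$y,
    R2X = (ssx_pred + ssx_orth) / ssx, R2Y = r2y,
    vip = vip, splot = splot, metabolites = colnames(X)),
    class = "oplsda")
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf(
    "# OPLS-DA fit: 1 predictive + %d orthogonal component(s), %d metabolites\n",
    x$n_orth, length(x$weights)))
  cat(sprintf("# R2X = %.3f, R2Y = %.3f (classes: %s vs %s)\n",
              x$R2X, x$R2Y, x$y_levels[1], x$y_levels[2]))
  invisible(x)
}

# Project new samples through the orthogonal filter, return predicted
# centred class response.
predict_oplsda_response <- function(object, newX) {
  Xd <- newX
  if (object$n_orth > 0) {
    for (k in seq_len(object$n_orth)) {
      t_o <- drop(Xd %*% object$orth_weights[, k])
      Xd <- Xd - tcrossprod(t_o, object$orth_loadings[, k])
    }
  }
  drop(Xd %*% object$weights) * object$q
}

#' @export
predict.oplsda <- function(object, newdata, ...) {
  newX <- if (inherits(newdata, "sample_table")) {
    metabolite_matrix(newdata)
  } else {
    as.matrix(newdata)
  }
  resp <- predict_oplsda_response(object, newX[, object$metabolites,
                                               drop = FALSE])
  ifelse(resp > 0, object$y_levels[2], object$y_levels[1])
}

#' VIP scores of a fitted OPLS-DA model
#'
#' Variable importance in projection on the predictive component. For a
#' single predictive component the score reduces to `sqrt(m) * |w_j|`
#' with `w` the unit predictive weight vector, so the mean squared VIP is
#' exactly 1; metabolites with VIP > 1 contribute more than average.
#'
#' @param model An `oplsda` fit.
#' @return Named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) model$vip

#' S-plot coordinates of a fitted OPLS-DA model
#'
#' Per metabolite, the covariance and the correlation of its (scaled)
#' values with the predictive score vector. Reliable, influential markers
#' sit at the extremes of both axes.
#'
#' @param model An `oplsda` fit.
#' @return Tibble `metabolite, covariance, correlation`.
#' @export
splot <- function(model) model$splot

#' Cross-validated Q2 of the class response
#'
#' `Q2 = 1 - PRESS / TSS` over held-out class predictions from k-fold
#' cross-validation stratified by class (every training split contains
#' both classes). Fold assignment is seeded and deterministic.
#'
#' @param x A preprocessed [sample_table()] or matrix.
#' @param y Group labels (ignored when `x` is a `sample_table`).
#' @param folds Number of folds (default 7).
#' @param seed Integer seed for fold assignment.
#' @param n_orth Orthogonal components per training fit.
#' @return Q2 (at most 1; can be negative for uninformative predictors).
#' @export
cross_validated_q2 <- function(x, y = NULL, folds = 7, seed = 1L,
                               n_orth = 1) {
  xy <- resolve_xy(x, y)
  X <- xy$X
  enc <- encode_class(xy$y)
  yc <- enc$y
  n <- nrow(X)
  stopifnot(folds >= 2)
  cls <- as.character(xy$y)
  if (min(table(cls)) < folds) {
    abort("each class needs at least `folds` samples for stratified CV")
  }
  fold_id <- integer(n)
  local_seed(seed, {
    for (lv in unique(cls)) {
      idx <- which(cls == lv)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  press <- 0
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fit <- opls_core(X[!test, , drop = FALSE], yc[!test] - mean(yc[!test]),
                     n_orth)
    Xd <- X[test, , drop = FALSE]
    if (n_orth > 0) {
      for (k in seq_len(n_orth)) {
        t_o <- drop(Xd %*% fit$W_o[, k])
        Xd <- Xd - tcrossprod(t_o, fit$P_o[, k])
      }
    }
    pred <- drop(Xd %*% fit$w) * fit$q + mean(yc[!test])
    press <- press + sum((yc[test] - pred)^2)
  }
  1 - press / sum((yc - mean(yc))^2)
}

#' Screen metabolites by VIP and Bonferroni-corrected univariate p
#'
#' A metabolite passes when its VIP exceeds 1 (strictly) and its
#' univariate Welch two-sample t-test p-value falls strictly below
#' `alpha / m` for `m` metabolites tested. The per-test threshold is
#' reported exactly and as its 2-significant-digit truncated display
#' (e.g. 0.05/168 = 2.976e-4, displayed 2.9e-4).
#'
#' @param x A preprocessed [sample_table()] or matrix.
#' @param y Group labels (ignored when `x` is a `sample_table`).
#' @param model Optional prefitted `oplsda`; fitted with defaults when
#'   `NULL`.
#' @param alpha Family-wise level (default 0.05).
#' @return Tibble `metabolite, vip, p_value, pass`, with attributes
#'   `threshold` (exact) and `threshold_display` (truncated).
#' @export
screen_metabolites <- function(x, y = NULL, model = NULL, alpha = 0.05) {
  xy <- resolve_xy(x, y)
  X <- xy$X
  if (is.null(model)) model <- fit_oplsda(X, xy$y)
  m <- ncol(X)
  thr <- alpha / m
  cls <- as.character(xy$y)
  lv <- model$y_levels
  p <- vapply(seq_len(m), function(j) {
    stats::t.test(X[cls == lv[1], j], X[cls == lv[2], j])$p.value
  }, 0)
  out <- tibble(metabolite = colnames(X),
                vip = unname(model$vip[colnames(X)]),
                p_value = p,
                pass = .data$vip > 1 & .data$p_value < thr)
  attr(out, "threshold") <- thr
  attr(out, "threshold_display") <- truncate_signif(thr, 2)
  out
}

# Truncate (not round) to `digits` significant digits: 2.976e-4 -> 2.9e-4.
truncate_signif <- function(x, digits = 2) {
  e <- floor(log10(abs(x))) - digits + 1
  trunc(x / 10^e) * 10^e
}

#' Covariate-adjusted association of candidate metabolites with group
#'
#' Ordinary least-squares of each candidate's covariate-adjusted level on
#' the binary group indicator (post = 1). With a binary predictor the
#' slope equals the difference of group means of the adjusted values; the
#' two-sided slope p-value tests the association with menopausal status.
#'
#' @param adjusted_table A [sample_table()] after [adjust_covariates()].
#' @param candidates Metabolite names to test (e.g. the screened set).
#' @return Tibble `metabolite, estimate, p_value`.
#' @export
associate <- function(adjusted_table, candidates) {
  mets <- metabolites(adjusted_table)
  absent <- setdiff(candidates, mets)
  if (length(absent) > 0) {
    abort(paste0("candidate metabolite(s) not in table: ",
                 paste(absent, collapse = ", ")))
  }
  vals <- metabolite_matrix(adjusted_table)
  g <- as.integer(adjusted_table$group == "post")
  purrr::map_dfr(candidates, function(m) {
    fit <- stats::lm(vals[, m] ~ g)
    sm <- summary(fit)$coefficients
    tibble(metabolite = m, estimate = sm["g", "Estimate"],
           p_value = sm["g", "Pr(>|t|)"])
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-metabolite summary of an OPLS-DA fit
#' @param x An `oplsda` fit.
#' @param ... Unused.
#' @return Tibble `metabolite, weight, loading, vip, covariance,
#'   correlation`.
#' @export
tidy.oplsda <- function(x, ...) {
  tibble(metabolite = x$metabolites,
         weight = unname(x$weights),
         loading = unname(x$loadings),
         vip = unname(x$vip)) |>
    left_join(x$splot, by = "metabolite")
}

#' One-row summary of an OPLS-DA fit
#' @param x An `oplsda` fit.
#' @param ... Unused.
#' @return Tibble `n_orth, R2X, R2Y`.
#' @export
glance.oplsda <- function(x, ...) {
  tibble(n_orth = x$n_orth, R2X = x$R2X, R2Y = x$R2Y)
}
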