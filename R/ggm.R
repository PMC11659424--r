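#' Arctangent penalty parameters
#'
#' The non-convex arctangent (atan) penalty
#' `p(theta) = lambda * (gamma + 2/pi) * atan(|theta| / gamma)` shrinks small
#' precision entries towards zero while its derivative vanishes for large
#' `|theta|`, leaving strong partial correlations nearly unshrunken ("nearly
#' unbiased" estimation). `gamma` controls how fast the shrinkage decays;
#' the default 0.01 follows the methodological recommendations this estimator
#' is built on.
#'
#' @param lambda regularization strength, `>= 0`.
#' @param gamma shape hyperparameter, `> 0` (default 0.01).
#' @return A `penalty_params` list.
#' @export
penalty_params <- function(lambda, gamma = 0.01) {
  stopifnot(length(lambda) == 1, lambda >= 0, length(gamma) == 1, gamma > 0)
  structure(list(lambda = lambda, gamma = gamma), class = "penalty_params")
}

#' @rdname penalty_params
#' @param theta precision-matrix entry (vectorized).
#' @param params a [penalty_params()].
#' @export
atan_penalty <- function(theta, params) {
  params$lambda * (params$gamma + 2 / pi) * atan(abs(theta) / params$gamma)
}

#' @rdname penalty_params
#' @export
atan_penalty_deriv <- function(theta, params) {
  params$lambda * (params$gamma + 2 / pi) * params$gamma /
    (params$gamma^2 + theta^2)
}

#' Intersubject correlation matrix of region uptake
#'
#' Pearson correlation of region columns across subjects — the "metabolic
#' connectivity" raw material: with one static image per subject, connectivity
#' is defined by covariation of regional uptake across participants.
#'
#' @param study a normalized [uptake_study()] with at least 3 subjects.
#' @return p x p correlation matrix with unit diagonal, dimnames = region ids.
#' @export
sample_correlation <- function(study) {
  stopifnot(inherits(study, "uptake_study"))
  if (!study$normalized) stop("study must be normalized before correlation")
  if (nrow(study$values) < 3) stop("need at least 3 subjects")
  v <- apply(study$values, 2, var)
  if (any(v < .Machine$double.eps)) {
    stop("zero-variance region(s): ",
         paste(colnames(study$values)[v < .Machine$double.eps], collapse = ", "))
  }
  r <- cor(study$values)
  diag(r) <- 1
  r
}

.check_corr <- function(corr, n) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr)) stop("correlation matrix must be square")
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-6) stop("correlation matrix must have unit diagonal")
  if (n < 3) stop("need n >= 3")
  0.5 * (corr + t(corr))
}

.ggm_fit_from_path <- function(res, corr, n, gamma, region_ids, edge_tol = 1e-8) {
  partial <- res$partial
  precision <- res$precision
  dimnames(partial) <- dimnames(precision) <- list(region_ids, region_ids)
  nz <- which(upper.tri(partial) & partial != 0, arr.ind = TRUE)
  edges <- cbind(from = region_ids[nz[, 1]], to = region_ids[nz[, 2]])
  bic_path <- data.frame(lambda = res$lambda, bic = res$bic,
                         n_edges = res$n_edges,
                         converged = res$converged == 1L)
  if (!bic_path$converged[res$best_index]) {
    warning("selected fit did not fully converge; returning last iterate")
  }
  structure(list(precision = precision, partial = partial,
                 lambda_selected = res$lambda[res$best_index],
                 gamma = gamma, bic_path = bic_path, edges = edges,
                 n = n, region_ids = region_ids),
            class = "ggm_fit")
}

#' Fit a sparse Gaussian graphical model at a single penalty value
#'
#' Solves the penalized Gaussian log-likelihood by local linear approximation
#' (LLA): the L1 (graphical lasso) solution at `lambda` initialises up to
#' `lla_max` weighted graphical-lasso iterations whose element penalties are
#' the atan derivative at the current precision entries. The diagonal is never
#' penalised; partial correlations below `1e-8` in magnitude are set to exact
#' zero. `penalty = "lasso"` skips the LLA stage and returns the convex L1
#' baseline (used internally for shrinkage comparisons).
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param n number of subjects behind `corr`.
#' @param params a [penalty_params()].
#' @param penalty `"atan"` (default) or `"lasso"`.
#' @param lla_max maximum LLA iterations (default 10).
#' @param lla_tol LLA convergence tolerance on `max |delta Theta|` (1e-4).
#' @return A `ggm_fit`: precision and partial-correlation matrices, the edge
#'   set (nonzero unordered pairs), the BIC bookkeeping, `n`, and region ids.
#' @export
fit_ggm_atan <- function(corr, n, params, penalty = c("atan", "lasso"),
                         lla_max = 10L, lla_tol = 1e-4) {
  penalty <- match.arg(penalty)
  corr <- .check_corr(corr, n)
  region_ids <- colnames(corr)
  if (is.null(region_ids)) region_ids <- paste0("V", seq_len(ncol(corr)))
  res <- .cpp_ggm_path(corr, as.integer(n), params$lambda, params$gamma,
                       if (penalty == "atan") as.integer(lla_max) else 0L,
                       lla_tol, 1e-4, 100L, 1e-8, 0L)
  .ggm_fit_from_path(res, corr, n, params$gamma, region_ids)
}

#' Fit a GGM with BIC selection of the penalty strength
#'
#' Fits the atan-penalized GGM along a descending lambda grid and returns the
#' fit minimising `BIC(lambda) = -2 * loglik + |E| * log(n)` with
#' `loglik = (n/2) * (log det Theta - trace(S Theta))` and `|E|` the number of
#' nonzero unordered off-diagonal pairs. Ties break towards larger lambda
#' (the sparser model). The default grid is 50 log-spaced values from
#' `lambda_max = max |offdiag(corr)|` down to `0.01 * lambda_max`.
#'
#' @inheritParams fit_ggm_atan
#' @param gamma atan shape hyperparameter.
#' @param grid optional strictly positive, strictly decreasing lambda grid.
#' @param n_lambda grid length when `grid` is NULL.
#' @param lambda_min_ratio grid floor as a fraction of `lambda_max`; the
#'   realized floor is the larger of this and half the theoretical rate
#'   `sqrt(log(p)/n)`, which keeps the bounded atan penalty away from the
#'   unbounded-likelihood regime on singular correlation input.
#' @param bic_early_stop if positive, stop descending the grid once the BIC
#'   has not improved for this many consecutive values (the skipped tail is
#'   `NaN` in `bic_path`); 0 fits the whole grid. Used inside permutation
#'   loops where thousands of refits make the idle tail expensive.
#' @return A `ggm_fit` at the BIC-optimal lambda, with the full `bic_path`.
#' @export
select_lambda_bic <- function(corr, n, gamma = 0.01, grid = NULL,
                              penalty = c("atan", "lasso"),
                              n_lambda = 50L, lambda_min_ratio = 0.01,
                              lla_max = 10L, lla_tol = 1e-4,
                              bic_early_stop = 0L) {
  penalty <- match.arg(penalty)
  corr <- .check_corr(corr, n)
  if (is.null(grid)) {
    grid <- .default_lambda_grid(corr, n, n_lambda, lambda_min_ratio)
  } else {
    if (length(grid) == 0) stop("empty lambda grid")
    if (any(grid <= 0)) stop("lambda grid must be strictly positive")
    if (length(grid) > 1 && any(diff(grid) >= 0)) {
      stop("lambda grid must be strictly decreasing")
    }
  }
  region_ids <- colnames(corr)
  if (is.null(region_ids)) region_ids <- paste0("V", seq_len(ncol(corr)))
  res <- .cpp_ggm_path(corr, as.integer(n), grid, gamma,
                       if (penalty == "atan") as.integer(lla_max) else 0L,
                       lla_tol, 1e-4, 100L, 1e-8, as.integer(bic_early_stop))
  .ggm_fit_from_path(res, corr, n, gamma, region_ids)
}

# Default descending lambda grid. The lower end is the larger of
# lambda_min_ratio * lambda_max and half the theoretical rate
# sqrt(log(p)/n): the atan penalty is bounded, so on a singular correlation
# matrix (n <= p, or the exact row-mean constraint of normalized uptake) the
# penalized likelihood is unbounded as lambda -> 0 and BIC would chase
# arbitrarily dense overfits down the grid; the rate floor keeps the grid in
# the regime where the estimator is defined.
.default_lambda_grid <- function(corr, n, n_lambda, lambda_min_ratio) {
  p <- ncol(corr)
  lmax <- max(abs(corr[upper.tri(corr)]), 1e-4)
  floor_theory <- 0.5 * sqrt(log(p) / n)
  lmin <- max(lambda_min_ratio * lmax, min(floor_theory, 0.5 * lmax))
  exp(seq(log(lmax), log(lmin), length.out = n_lambda))
}

#' Construct a brain network from an edge-weight matrix
#'
#' Low-level constructor used by [fit_group_network()] and by tests that need
#' hand-built graphs. Weights are symmetric signed partial correlations with a
#' zero diagonal.
#'
#' @param weights symmetric numeric matrix, zero diagonal.
#' @param region_ids optional region ids (default from dimnames).
#' @param group group label attached to the network.
#' @param fit optional `ggm_fit` behind the weights.
#' @param atlas optional [region_atlas()] for the regions.
#' @param covariate_adjusted_for covariate names conditioned on (possibly none).
#' @return A `brain_network`.
#' @export
brain_network <- function(weights, region_ids = NULL, group = "CTRL",
                          fit = NULL, atlas = NULL,
                          covariate_adjusted_for = character()) {
  weights <- as.matrix(weights)
  if (max(abs(weights - t(weights))) > 1e-10) stop("weights must be symmetric")
  weights <- 0.5 * (weights + t(weights))   # drop float-level asymmetry
  diag(weights) <- 0
  if (is.null(region_ids)) region_ids <- colnames(weights)
  if (is.null(region_ids)) region_ids <- paste0("V", seq_len(ncol(weights)))
  dimnames(weights) <- list(region_ids, region_ids)
  structure(list(weights = weights, region_ids = region_ids, group = group,
                 fit = fit, atlas = atlas,
                 covariate_adjusted_for = covariate_adjusted_for),
            class = "brain_network")
}

#' Estimate one group's metabolic network, optionally covariate-adjusted
#'
#' Runs [select_lambda_bic()] on the group's region correlation matrix. When
#' `adjust_for` is non-empty the covariates (e.g. `"cpz_equiv"`,
#' chlorpromazine-equivalent dose) enter the estimation as additional nodes of
#' the graphical model; after fitting, the covariate rows/columns are deleted,
#' so the retained region-region partial correlations are conditioned on the
#' covariates — node augmentation followed by node removal, not
#' residualization.
#'
#' @param study a normalized [uptake_study()].
#' @param group group label to estimate.
#' @param adjust_for character vector of covariate names (`"cpz_equiv"` or any
#'   optional covariate column); must be present and non-constant within the
#'   group.
#' @param gamma,n_lambda,lambda_min_ratio,penalty,lla_max,bic_early_stop
#'   passed to [select_lambda_bic()].
#' @return A [brain_network()] whose `weights` are the region-block partial
#'   correlations (zero diagonal) and whose `covariate_adjusted_for` records
#'   the adjustment.
#' @export
fit_group_network <- function(study, group, adjust_for = character(),
                              gamma = 0.01, n_lambda = 50L,
                              lambda_min_ratio = 0.01,
                              penalty = "atan", lla_max = 10L,
                              bic_early_stop = 0L) {
  stopifnot(inherits(study, "uptake_study"))
  if (!study$normalized) stop("study must be normalized before network estimation")
  sub <- subset_study(study, group = group)
  p <- ncol(sub$values)
  x <- sub$values
  if (length(adjust_for) > 0) {
    for (cv in adjust_for) {
      col <- sub$subjects[[cv]]
      if (is.null(col)) stop("covariate '", cv, "' is not recorded for group ", group)
      if (anyNA(col)) stop("covariate '", cv, "' has missing values in group ", group)
      if (sd(col) < .Machine$double.eps) {
        stop("covariate '", cv, "' is constant within group ", group)
      }
      x <- cbind(x, col)
      colnames(x)[ncol(x)] <- cv
    }
  }
  v <- apply(x, 2, var)
  if (any(v < .Machine$double.eps)) {
    stop("zero-variance column(s): ", paste(colnames(x)[v < 1e-300], collapse = ", "))
  }
  corr <- cor(x)
  diag(corr) <- 1
  fit <- select_lambda_bic(corr, n = nrow(x), gamma = gamma,
                           penalty = penalty, n_lambda = n_lambda,
                           lambda_min_ratio = lambda_min_ratio,
                           lla_max = lla_max, bic_early_stop = bic_early_stop)
  keep <- seq_len(p)
  partial <- fit$partial[keep, keep, drop = FALSE]
  fit$precision <- fit$precision[keep, keep, drop = FALSE]
  fit$partial <- partial
  fit$region_ids <- colnames(partial)
  nz <- which(upper.tri(partial) & partial != 0, arr.ind = TRUE)
  fit$edges <- cbind(from = fit$region_ids[nz[, 1]], to = fit$region_ids[nz[, 2]])
  weights <- partial
  diag(weights) <- 0
  brain_network(weights, region_ids = colnames(partial), group = group,
                fit = fit, atlas = sub$atlas,
                covariate_adjusted_for = adjust_for)
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat("<ggm_fit> p=", length(x$region_ids), ", n=", x$n,
      ", lambda=", signif(x$lambda_selected, 4), ", gamma=", x$gamma,
      ", edges=", nrow(x$edges), "\n", sep = "")
  invisible(x)
}

#' @export
print.brain_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("<brain_network> group=", x$group, ", p=", length(x$region_ids),
      ", edges=", ne,
      if (length(x$covariate_adjusted_for) > 0)
        paste0(", adjusted for: ", paste(x$covariate_adjusted_for, collapse = ", "))
      else "", "\n", sep = "")
  invisible(x)
}

#' Export a brain network
#'
#' `write_network_graphml` writes a GraphML file with signed partial
#' correlations as the `weight` edge attribute; `write_network_csv` writes the
#' square weight matrix; `write_brainnet` writes BrainNet-Viewer-style
#' plain-text `.node` / `.edge` files (node size = weighted degree, node color
#' = module index; coordinates are synthetic placeholders on a circle since no
#' stereotactic space is attached).
#'
#' @param net a [brain_network()].
#' @param path output file path (for `write_brainnet`, a prefix without
#'   extension).
#' @return The written path(s), invisibly.
#' @export
write_network_graphml <- function(net, path) {
  g <- .net_igraph(net, weighted = TRUE, signed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_csv <- function(net, path) {
  write.csv(as.data.frame(net$weights), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_brainnet <- function(net, path) {
  p <- length(net$region_ids)
  angle <- 2 * pi * (seq_len(p) - 1) / p
  coords <- cbind(round(80 * cos(angle), 3), round(80 * sin(angle), 3), 0)
  module <- if (!is.null(net$atlas)) {
    as.integer(factor(net$atlas$module_label))
  } else rep(1L, p)
  size <- rowSums(abs(net$weights))
  node <- data.frame(coords[, 1], coords[, 2], coords[, 3],
                     module, round(size, 6), net$region_ids)
  node_path <- paste0(path, ".node")
  edge_path <- paste0(path, ".edge")
  write.table(node, node_path, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  write.table(round(net$weights, 8), edge_path, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(c(node = node_path, edge = edge_path))
}

# igraph view of a network; binarized or weighted on |w|
.net_igraph <- function(net, weighted = FALSE, signed = FALSE) {
  w <- net$weights
  adj <- if (weighted) {
    if (signed) w else abs(w)
  } else (w != 0) * 1
  mode <- "undirected"
  g <- igraph::graph_from_adjacency_matrix(adj, mode = mode,
                                           weighted = if (weighted) TRUE else NULL,
                                           diag = FALSE)
  g
}
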