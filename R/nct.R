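#' Network comparison test configuration
#'
#' @param n_perm number of label permutations (default 10000; >= 100).
#' @param statistics subset of `"global_strength"`, `"node_strength"`,
#'   `"edges"`.
#' @param adjust_method multiple-testing adjustment for the node and edge
#'   families: `"benjamini-hochberg"` (default) or `"holm"`.
#' @param alpha significance threshold echoed into outputs.
#' @param covariates covariate names entering estimation as nodes (e.g.
#'   `"cpz_equiv"`); removed after fitting, see [fit_group_network()].
#' @param subnetwork `"none"`, `"dmn"`, `"ddp"`, or a character vector of
#'   region ids; restricts the statistic (and adjustment) families to
#'   within-subnetwork nodes/edges.
#' @param seed RNG seed; the full test is deterministic given it.
#' @param n_lambda,gamma,lambda_min_ratio estimation settings forwarded to
#'   [select_lambda_bic()] — the penalty strength is re-selected by BIC inside
#'   every permutation, so the null reproduces the whole estimation pipeline.
#' @param bic_early_stop forwarded to [select_lambda_bic()]: abandon the
#'   descending grid after this many consecutive non-improving BIC values
#'   (default 6), trimming the idle tail of each of the thousands of
#'   permutation refits without changing which lambda wins.
#' @return An `nct_config` list.
#' @export
nct_config <- function(n_perm = 10000L,
                       statistics = c("global_strength", "node_strength", "edges"),
                       adjust_method = c("benjamini-hochberg", "holm"),
                       alpha = 0.05, covariates = character(),
                       subnetwork = "none", seed = 1L,
                       n_lambda = 50L, gamma = 0.01, lambda_min_ratio = 0.01,
                       bic_early_stop = 6L) {
  adjust_method <- match.arg(adjust_method)
  statistics <- match.arg(statistics, several.ok = TRUE)
  stopifnot(n_perm >= 100, alpha > 0, alpha < 1)
  structure(list(n_perm = as.integer(n_perm), statistics = statistics,
                 adjust_method = adjust_method, alpha = alpha,
                 covariates = covariates, subnetwork = subnetwork,
                 seed = as.integer(seed), n_lambda = as.integer(n_lambda),
                 gamma = gamma, lambda_min_ratio = lambda_min_ratio,
                 bic_early_stop = as.integer(bic_early_stop)),
            class = "nct_config")
}

#' Global strength of a network
#'
#' Sum of absolute edge weights over unique (unordered) edges, optionally
#' restricted to edges with both endpoints in a subnetwork.
#'
#' @param net a [brain_network()].
#' @param subnetwork optional character vector of region ids.
#' @return Non-negative scalar.
#' @export
global_strength <- function(net, subnetwork = NULL) {
  stopifnot(inherits(net, "brain_network"))
  w <- abs(net$weights)
  if (!is.null(subnetwork)) {
    keep <- net$region_ids %in% subnetwork
    if (!any(keep)) return(0)
    w <- w[keep, keep, drop = FALSE]
  }
  sum(w[upper.tri(w)])
}

#' Adjust permutation p-values for multiple testing
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @param method `"benjamini-hochberg"` or `"holm"`.
#' @return Adjusted p-values, clipped to (0, 1]; empty input gives empty
#'   output.
#' @export
adjust_pvalues <- function(p, method = c("benjamini-hochberg", "holm")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  pmin(stats::p.adjust(p, method = if (method == "holm") "holm" else "BH"), 1)
}

.resolve_subnetwork <- function(study, subnetwork) {
  if (is.null(subnetwork) || identical(subnetwork, "none")) {
    return(study$atlas$region_id)
  }
  if (length(subnetwork) == 1 && subnetwork %in% c("dmn", "ddp")) {
    return(subnetwork_regions(study$atlas, subnetwork))
  }
  bad <- setdiff(subnetwork, study$atlas$region_id)
  if (length(bad) > 0) stop("unknown subnetwork region(s): ",
                            paste(bad, collapse = ", "))
  subnetwork
}

# statistic vector(s) for one pair of weight matrices, restricted to the
# region indices `ridx` (weights are full-atlas, region-named, zero-diagonal)
.nct_stats_w <- function(wA, wB, ridx, statistics) {
  out <- list()
  regions <- colnames(wA)[ridx]
  if ("node_strength" %in% statistics || "global_strength" %in% statistics) {
    aA <- abs(wA); aB <- abs(wB)
  }
  if ("global_strength" %in% statistics) {
    sA <- aA[ridx, ridx, drop = FALSE]
    sB <- aB[ridx, ridx, drop = FALSE]
    out$global_strength <- abs(sum(sA[upper.tri(sA)]) - sum(sB[upper.tri(sB)]))
  }
  if ("node_strength" %in% statistics) {
    out$node_strength <- setNames(abs(rowSums(aA)[ridx] - rowSums(aB)[ridx]),
                                  regions)
  }
  if ("edges" %in% statistics) {
    d <- abs(abs(wA[ridx, ridx, drop = FALSE]) -
               abs(wB[ridx, ridx, drop = FALSE]))
    ut <- which(upper.tri(d), arr.ind = TRUE)
    out$edges <- setNames(d[upper.tri(d)],
                          paste(regions[ut[, 1]], regions[ut[, 2]], sep = "--"))
  }
  out
}

# one lean estimation for the permutation loop: identical grid construction
# and C++ path as select_lambda_bic, without the bookkeeping layers
.nct_weights <- function(x, n_regions, config) {
  corr <- cor(x)
  diag(corr) <- 1
  grid <- .default_lambda_grid(corr, nrow(x), config$n_lambda,
                               config$lambda_min_ratio)
  res <- .cpp_ggm_path(corr, nrow(x), grid, config$gamma, 10L, 1e-4,
                       1e-4, 100L, 1e-8, config$bic_early_stop)
  w <- res$partial[seq_len(n_regions), seq_len(n_regions), drop = FALSE]
  diag(w) <- 0
  dimnames(w) <- list(colnames(x)[seq_len(n_regions)],
                      colnames(x)[seq_len(n_regions)])
  list(w = w, converged = res$converged[res$best_index] == 1L)
}

#' Permutation-based comparison of two group networks
#'
#' Estimates each group's network with the full pipeline (BIC-selected
#' atan-penalized GGM, optional covariate nodes), then builds an empirical
#' null by pooling the two groups' subjects, reassigning group labels at
#' random (group sizes preserved, each subject keeping its covariate values)
#' and re-running the entire estimation — penalty re-selection included — in
#' every permutation. Test statistics are absolute differences: global
#' strength `|S_A - S_B|`, per-node weighted degree `|d_Ai - d_Bi|`, per-edge
#' `||w_Aij| - |w_Bij||`. P-values use the add-one convention
#' `(1 + #(null >= obs)) / (1 + n_perm)`; node and edge families are adjusted
#' by `config$adjust_method`.
#'
#' @param study a normalized [uptake_study()] containing both groups.
#' @param groupA,groupB group labels (each with at least 5 subjects).
#' @param config an [nct_config()].
#' @return An `nct_result`: observed statistics, permutation null
#'   distributions, `p_global`, `p_nodes` and `p_edges` data.frames
#'   (raw and adjusted), the groups and the config echo.
#' @export
compare_networks <- function(study, groupA, groupB, config = nct_config()) {
  res <- compare_networks_multi(study, groupA, groupB, config,
                                subnetworks = list(config$subnetwork))
  res[[1]]
}

#' Compare two group networks under several subnetwork restrictions at once
#'
#' Runs the identical permutation machinery as [compare_networks()] but
#' evaluates every requested restriction from the same permutation stream of
#' full-pipeline refits — with restrictions being cheap functions of the
#' fitted weight matrices, this divides the cost of a whole-brain + DMN + DDP
#' analysis by the number of restrictions.
#'
#' @inheritParams compare_networks
#' @param subnetworks list of restrictions (each `"none"`, `"dmn"`, `"ddp"`,
#'   or a region-id vector).
#' @return Named list of `nct_result`, one per restriction.
#' @export
compare_networks_multi <- function(study, groupA, groupB,
                                   config = nct_config(),
                                   subnetworks = list("none")) {
  stopifnot(inherits(study, "uptake_study"), inherits(config, "nct_config"))
  if (!study$normalized) stop("study must be normalized")
  pooled <- subset_study(study, group = c(groupA, groupB))
  grp <- pooled$subjects$group
  nA <- sum(grp == groupA)
  nB <- sum(grp == groupB)
  if (nA < 5 || nB < 5) stop("each group needs at least 5 subjects")
  for (cv in config$covariates) {
    col <- pooled$subjects[[cv]]
    if (is.null(col) || anyNA(col)) stop("covariate '", cv, "' missing in pooled sample")
    if (sd(col) < .Machine$double.eps) {
      stop("covariate '", cv, "' is constant in the pooled sample")
    }
  }
  region_sets <- lapply(subnetworks, function(sn) .resolve_subnetwork(pooled, sn))
  if (is.null(names(region_sets))) {
    names(region_sets) <- vapply(subnetworks, function(sn) {
      if (length(sn) == 1 && is.character(sn)) sn else "custom"
    }, character(1))
  }
  for (rs in region_sets) {
    if (length(rs) < 2) stop("subnetwork restriction leaves fewer than 2 regions")
  }

  fit_one <- function(st, g) {
    fit_group_network(st, g, adjust_for = config$covariates,
                      gamma = config$gamma, n_lambda = config$n_lambda,
                      lambda_min_ratio = config$lambda_min_ratio,
                      bic_early_stop = config$bic_early_stop)
  }
  netA <- fit_one(pooled, groupA)
  netB <- fit_one(pooled, groupB)
  ridx_sets <- lapply(region_sets, match, pooled$atlas$region_id)

  # permutation loop operates on the raw matrix: region columns plus any
  # covariate columns, each subject keeping its covariate values
  xmat <- pooled$values
  if (length(config$covariates) > 0) {
    for (cv in config$covariates) {
      xmat <- cbind(xmat, pooled$subjects[[cv]])
      colnames(xmat)[ncol(xmat)] <- cv
    }
  }
  n_regions <- ncol(pooled$values)
  is_A <- grp == groupA

  obs_w <- list(.nct_weights(xmat[is_A, , drop = FALSE], n_regions, config),
                .nct_weights(xmat[!is_A, , drop = FALSE], n_regions, config))
  # the rich fit and the lean loop must agree exactly
  stopifnot(max(abs(obs_w[[1]]$w - netA$weights)) < 1e-12,
            max(abs(obs_w[[2]]$w - netB$weights)) < 1e-12)
  obs <- lapply(ridx_sets, function(ri) {
    .nct_stats_w(obs_w[[1]]$w, obs_w[[2]]$w, ri, config$statistics)
  })

  set.seed(config$seed)
  perms <- replicate(config$n_perm, sample(grp), simplify = FALSE)

  null <- lapply(ridx_sets, function(ri) {
    list(global = numeric(0), nodes = NULL, edges = NULL)
  })
  n_unconverged <- 0L
  for (b in seq_len(config$n_perm)) {
    pa <- perms[[b]] == groupA
    fa <- .nct_weights(xmat[pa, , drop = FALSE], n_regions, config)
    fb <- .nct_weights(xmat[!pa, , drop = FALSE], n_regions, config)
    if (!fa$converged || !fb$converged) n_unconverged <- n_unconverged + 1L
    for (k in seq_along(ridx_sets)) {
      s <- .nct_stats_w(fa$w, fb$w, ridx_sets[[k]], config$statistics)
      if (!is.null(s$global_strength)) null[[k]]$global[b] <- s$global_strength
      if (!is.null(s$node_strength)) {
        null[[k]]$nodes <- rbind(null[[k]]$nodes, s$node_strength)
      }
      if (!is.null(s$edges)) null[[k]]$edges <- rbind(null[[k]]$edges, s$edges)
    }
  }
  if (n_unconverged > 0) {
    message("note: ", n_unconverged, " permutation fit(s) returned a ",
            "not-fully-converged iterate")
  }

  perm_p <- function(obs_v, null_m) {
    vapply(seq_along(obs_v), function(i) {
      (1 + sum(null_m[, i] >= obs_v[i])) / (1 + config$n_perm)
    }, numeric(1))
  }

  out <- vector("list", length(ridx_sets))
  names(out) <- names(region_sets)
  for (k in seq_along(ridx_sets)) {
    ob <- obs[[k]]
    nl <- null[[k]]
    p_global <- NULL
    p_nodes <- NULL
    p_edges <- NULL
    if ("global_strength" %in% config$statistics) {
      p_global <- (1 + sum(nl$global >= ob$global_strength)) / (1 + config$n_perm)
    }
    if ("node_strength" %in% config$statistics) {
      raw <- perm_p(ob$node_strength, nl$nodes)
      p_nodes <- data.frame(region_id = names(ob$node_strength),
                            observed = unname(ob$node_strength),
                            p_raw = raw,
                            p_adjusted = adjust_pvalues(raw, config$adjust_method),
                            stringsAsFactors = FALSE)
    }
    if ("edges" %in% config$statistics) {
      raw <- perm_p(ob$edges, nl$edges)
      pair <- do.call(rbind, strsplit(names(ob$edges), "--", fixed = TRUE))
      p_edges <- data.frame(from = pair[, 1], to = pair[, 2],
                            observed = unname(ob$edges),
                            p_raw = raw,
                            p_adjusted = adjust_pvalues(raw, config$adjust_method),
                            stringsAsFactors = FALSE)
    }
    cfg_k <- config
    cfg_k$subnetwork <- if (is.character(subnetworks[[k]]) &&
                              length(subnetworks[[k]]) == 1) {
      subnetworks[[k]]
    } else "custom"
    out[[k]] <- structure(
      list(groups = c(groupA, groupB), observed = ob,
           null_distributions = list(global_strength = nl$global,
                                     node_strength = nl$nodes,
                                     edges = nl$edges),
           p_global = p_global, p_nodes = p_nodes, p_edges = p_edges,
           regions = region_sets[[k]], config = cfg_k,
           networks = list(netA, netB)),
      class = "nct_result")
  }
  out
}

#' @export
print.nct_result <- function(x, ...) {
  cat("<nct_result> ", x$groups[1], " vs ", x$groups[2],
      " (", x$config$n_perm, " permutations",
      if (length(x$config$covariates) > 0)
        paste0(", adjusted for ", paste(x$config$covariates, collapse = ", "))
      else "", ")\n", sep = "")
  if (!is.null(x$p_global)) {
    cat("  global strength: |diff| = ",
        signif(x$observed$global_strength, 4),
        ", p = ", signif(x$p_global, 4), "\n", sep = "")
  }
  if (!is.null(x$p_nodes)) {
    cat("  nodes with adjusted p < ", x$config$alpha, ": ",
        sum(x$p_nodes$p_adjusted < x$config$alpha), "/", nrow(x$p_nodes),
        "\n", sep = "")
  }
  if (!is.null(x$p_edges)) {
    cat("  edges with adjusted p < ", x$config$alpha, ": ",
        sum(x$p_edges$p_adjusted < x$config$alpha), "/", nrow(x$p_edges),
        "\n", sep = "")
  }
  invisible(x)
}

#' Write NCT results to plain-text files
#'
#' Writes `nct_summary.json` (global statistic and p-value, config echo),
#' `nct_nodes.csv` / `nct_edges.csv` (one row per node/edge with raw and
#' adjusted p and a significance column at `alpha`), and
#' `nct_edge_pmatrix.csv` (square adjusted-p matrix over the restricted
#' regions).
#'
#' @param res an `nct_result`.
#' @param dir output directory (created if absent).
#' @param prefix filename prefix.
#' @return Written paths, invisibly.
#' @export
write_nct_results <- function(res, dir, prefix = "nct") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  summ <- list(groups = res$groups,
               global_strength_diff = res$observed$global_strength,
               p_global = res$p_global,
               n_perm = res$config$n_perm,
               adjust_method = res$config$adjust_method,
               alpha = res$config$alpha,
               covariates = res$config$covariates,
               subnetwork = res$config$subnetwork,
               seed = res$config$seed)
  sp <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(summ, sp, auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(paths, sp)
  if (!is.null(res$p_nodes)) {
    df <- res$p_nodes
    df$significant <- df$p_adjusted < res$config$alpha
    np <- file.path(dir, paste0(prefix, "_nodes.csv"))
    write.csv(df, np, row.names = FALSE)
    paths <- c(paths, np)
  }
  if (!is.null(res$p_edges)) {
    df <- res$p_edges
    df$significant <- df$p_adjusted < res$config$alpha
    ep <- file.path(dir, paste0(prefix, "_edges.csv"))
    write.csv(df, ep, row.names = FALSE)
    paths <- c(paths, ep)
    r <- res$regions
    m <- matrix(1, length(r), length(r), dimnames = list(r, r))
    for (i in seq_len(nrow(df))) {
      m[df$from[i], df$to[i]] <- df$p_adjusted[i]
      m[df$to[i], df$from[i]] <- df$p_adjusted[i]
    }
    mp <- file.path(dir, paste0(prefix, "_edge_pmatrix.csv"))
    write.csv(as.data.frame(m), mp, row.names = TRUE)
    paths <- c(paths, mp)
  }
  invisible(paths)
}
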