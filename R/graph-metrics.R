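# Descriptive graph analytics. Binary-topology metrics (density, clustering,
# path length, small-worldness, robustness) are computed on the binarized
# nonzero-edge graph; degree/strength-type metrics use absolute edge weights.

# largest-connected-component trajectory for one removal order, via
# reverse-order union-find (nodes are added back one at a time)
.lcc_trajectory <- function(adj, order) {
  p <- nrow(adj)
  parent <- integer(p)
  size <- integer(p)
  present <- logical(p)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  lcc <- numeric(p + 1)   # lcc[k+1] = LCC size with k nodes present
  lcc[1] <- 0
  best <- 0
  for (k in seq_len(p)) {
    v <- order[p - k + 1]   # reverse removal = addition
    present[v] <- TRUE
    parent[v] <- v
    size[v] <- 1L
    for (u in which(adj[v, ] & present)) {
      ru <- find(u); rv <- find(v)
      if (ru != rv) {
        if (size[ru] < size[rv]) { tmp <- ru; ru <- rv; rv <- tmp }
        parent[rv] <- ru
        size[ru] <- size[ru] + size[rv]
      }
    }
    best <- max(best, size[find(v)])
    lcc[k + 1] <- best
  }
  # trajectory after removing 0..p-1 nodes = p, p-1, ..., 1 nodes present
  rev(lcc[-1])
}

# all permutations of 1..n (used only when n! is small)
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  out
}

#' Summary of a network's global topological properties
#'
#' Computes on the binarized (nonzero-weight) graph: edge count and density;
#' global clustering coefficient (transitivity, 3 * triangles / connected
#' triples); average shortest path length over connected pairs only, with the
#' fraction of disconnected pairs reported alongside; robustness (mean over
#' node-removal orders of the normalized largest-connected-component size,
#' averaged along the removal sequence); and the small-worldness index
#' `sigma = (C / <C_rand>) / (L / <L_rand>)` against degree-preserving rewired
#' reference graphs.
#'
#' Removal orders are enumerated exhaustively when `factorial(p) <= n_orders`
#' (exact expectation), otherwise sampled under `seed`.
#'
#' @param net a [brain_network()] with at least 3 nodes.
#' @param n_ref number of rewired reference graphs for small-worldness.
#' @param n_orders number of random node-removal orders for robustness.
#' @param seed RNG seed for removal orders and rewiring.
#' @return A `graph_summary` list: `n_edges`, `edge_density`,
#'   `global_clustering`, `avg_shortest_path`, `frac_disconnected_pairs`,
#'   `small_worldness`, `robustness`. Path length and small-worldness are
#'   `NaN` with `degenerate = TRUE` when the graph has no edges.
#' @export
summarize_graph <- function(net, n_ref = 100L, n_orders = 500L, seed = 1L) {
  stopifnot(inherits(net, "brain_network"))
  p <- length(net$region_ids)
  if (p < 3) stop("need at least 3 nodes")
  adj <- net$weights != 0
  diag(adj) <- FALSE
  n_edges <- sum(adj[upper.tri(adj)])
  density <- n_edges / (p * (p - 1) / 2)
  g <- .net_igraph(net)

  clustering <- if (n_edges == 0) 0 else {
    tr <- igraph::transitivity(g, type = "global")
    if (is.nan(tr)) 0 else tr
  }

  if (n_edges == 0) {
    asp <- NaN
    frac_disc <- 1
  } else {
    d <- igraph::distances(g)
    off <- d[upper.tri(d)]
    finite <- is.finite(off)
    asp <- if (any(finite)) mean(off[finite]) else NaN
    frac_disc <- mean(!finite)
  }

  set.seed(seed)
  n_fact <- if (p <= 12) factorial(p) else Inf
  orders <- if (n_fact <= n_orders) {
    perms <- .all_perms(p)
    lapply(seq_len(nrow(perms)), function(i) perms[i, ])
  } else {
    lapply(seq_len(n_orders), function(i) sample.int(p))
  }
  traj <- vapply(orders, function(o) mean(.lcc_trajectory(adj, o)) / p,
                 numeric(1))
  robustness <- mean(traj)

  sw <- NaN
  if (n_edges > 0 && is.finite(asp) && clustering > 0) {
    c_rand <- numeric(n_ref)
    l_rand <- numeric(n_ref)
    for (i in seq_len(n_ref)) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = max(100, 10 * n_edges)))
      tr <- igraph::transitivity(gr, type = "global")
      c_rand[i] <- if (is.nan(tr)) 0 else tr
      dr <- igraph::distances(gr)
      offr <- dr[upper.tri(dr)]
      l_rand[i] <- if (any(is.finite(offr))) mean(offr[is.finite(offr)]) else NA
    }
    cm <- mean(c_rand)
    lm <- mean(l_rand, na.rm = TRUE)
    if (is.finite(cm) && cm > 0 && is.finite(lm) && lm > 0) {
      sw <- (clustering / cm) / (asp / lm)
    }
  }

  structure(list(n_edges = n_edges, edge_density = density,
                 global_clustering = clustering, avg_shortest_path = asp,
                 frac_disconnected_pairs = frac_disc,
                 small_worldness = sw, robustness = robustness,
                 degenerate = n_edges == 0),
            class = "graph_summary")
}

#' @export
print.graph_summary <- function(x, ...) {
  cat("<graph_summary> edges=", x$n_edges,
      " density=", signif(x$edge_density, 3),
      " C=", signif(x$global_clustering, 3),
      " L=", signif(x$avg_shortest_path, 4),
      " (", signif(x$frac_disconnected_pairs, 3), " pairs disconnected)",
      " sigma=", signif(x$small_worldness, 3),
      " robustness=", signif(x$robustness, 4), "\n", sep = "")
  invisible(x)
}

#' Weighted degree (node strength)
#'
#' Sum of absolute incident edge weights per node.
#'
#' @param net a [brain_network()].
#' @return Named numeric vector over region ids.
#' @export
weighted_degree <- function(net) {
  stopifnot(inherits(net, "brain_network"))
  setNames(rowSums(abs(net$weights)), net$region_ids)
}

#' Louvain community partition on absolute weights
#'
#' Modularity-maximizing partition (resolution 1) of the absolute-weight
#' graph. The Louvain heuristic depends on the node sweep order; `n_starts`
#' seeded restarts are run and the partition with the highest modularity kept
#' (first winner on ties), which reliably reaches the optimum on small graphs
#' where a single sweep can stall. Deterministic under `seed`. An edgeless
#' graph puts every node in its own community.
#'
#' @param net a [brain_network()].
#' @param seed RNG seed; restart r uses `seed + r - 1`.
#' @param n_starts number of restarts (default 5).
#' @return A `community_partition`: `assignment` (named integer vector,
#'   communities indexed contiguously from 0), `method`, `seed`.
#' @export
louvain_partition <- function(net, seed = 1L, n_starts = 5L) {
  stopifnot(inherits(net, "brain_network"))
  p <- length(net$region_ids)
  n_edges <- sum(net$weights[upper.tri(net$weights)] != 0)
  if (n_edges == 0) {
    member <- seq_len(p) - 1L
  } else {
    g <- .net_igraph(net, weighted = TRUE, signed = FALSE)
    ew <- igraph::E(g)$weight
    best_q <- -Inf
    member <- NULL
    for (r in seq_len(n_starts)) {
      set.seed(seed + r - 1L)
      cl <- igraph::cluster_louvain(g, weights = ew)
      q <- igraph::modularity(g, igraph::membership(cl), weights = ew)
      if (q > best_q + 1e-12) {
        best_q <- q
        m <- igraph::membership(cl)
        member <- as.integer(factor(m, levels = unique(m))) - 1L
      }
    }
  }
  structure(list(assignment = setNames(member, net$region_ids),
                 method = "louvain", seed = as.integer(seed)),
            class = "community_partition")
}

.grouping_vector <- function(net, grouping) {
  if (inherits(grouping, "community_partition")) {
    return(grouping$assignment[net$region_ids])
  }
  if (is.null(names(grouping))) stop("grouping must be named by region id")
  grouping[intersect(net$region_ids, names(grouping))]
}

#' Within-community average degree
#'
#' For each community, the mean over member nodes of their within-community
#' binary degree divided by (community size - 1) — a density-like value in
#' `[0, 1]` comparable across communities of different sizes. `grouping` may
#' be a [louvain_partition()] or any named label vector; a label vector
#' covering only a subset of nodes restricts the computation to that subset
#' (the subnetwork mode used for DMN / dorsal-dopamine-pathway tables).
#'
#' @param net a [brain_network()].
#' @param grouping a `community_partition` or named vector of labels.
#' @return Named numeric vector, one value per community.
#' @export
community_average_degree <- function(net, grouping) {
  stopifnot(inherits(net, "brain_network"))
  gv <- .grouping_vector(net, grouping)
  adj <- net$weights != 0
  out <- numeric(0)
  for (comm in unique(gv)) {
    members <- names(gv)[gv == comm]
    idx <- match(members, net$region_ids)
    m <- length(idx)
    if (m == 1) {
      warning("singleton community '", comm, "'; average degree set to 0")
      out[as.character(comm)] <- 0
      next
    }
    deg <- rowSums(adj[idx, idx, drop = FALSE])
    out[as.character(comm)] <- mean(deg / (m - 1))
  }
  out
}

#' Participation coefficients
#'
#' `P_i = 1 - sum_s (k_is / k_i)^2` with `k` absolute-weight strengths and `s`
#' running over communities. A node whose connections all stay inside its own
#' community has `P_i = 0`; spreading strength evenly over `s` communities
#' gives `1 - 1/s`. Isolated nodes get 0.
#'
#' @param net a [brain_network()].
#' @param partition a [louvain_partition()] (or compatible named assignment).
#' @return Named numeric vector over region ids.
#' @export
participation_coefficients <- function(net, partition) {
  stopifnot(inherits(net, "brain_network"))
  assign <- if (inherits(partition, "community_partition")) {
    partition$assignment
  } else partition
  missing <- setdiff(net$region_ids, names(assign))
  if (length(missing) > 0) {
    stop("partition does not cover node(s): ", paste(missing, collapse = ", "))
  }
  assign <- assign[net$region_ids]
  w <- abs(net$weights)
  k <- rowSums(w)
  pc <- numeric(length(k))
  comms <- unique(assign)
  for (s in comms) {
    k_is <- rowSums(w[, assign == s, drop = FALSE])
    nz <- k > 0
    pc[nz] <- pc[nz] + (k_is[nz] / k[nz])^2
  }
  out <- ifelse(k > 0, 1 - pc, 0)
  setNames(out, net$region_ids)
}

#' Hub identification by the participation-coefficient rule
#'
#' A node is a hub when its participation coefficient exceeds the mean by more
#' than one (sample) standard deviation. With a constant coefficient vector
#' (sd = 0) no node qualifies (strict inequality).
#'
#' @param pc named participation-coefficient vector (from
#'   [participation_coefficients()]).
#' @param wdeg optional named weighted-degree vector to carry along.
#' @return A `hub_table` data.frame: `region_id`,
#'   `participation_coefficient`, `weighted_degree`, `is_hub`.
#' @export
identify_hubs <- function(pc, wdeg = NULL) {
  if (length(pc) < 2) stop("need at least 2 nodes")
  thr <- mean(pc) + sd(pc)
  if (is.null(wdeg)) wdeg <- setNames(rep(NA_real_, length(pc)), names(pc))
  out <- data.frame(region_id = names(pc),
                    participation_coefficient = unname(pc),
                    weighted_degree = unname(wdeg[names(pc)]),
                    is_hub = unname(pc > thr),
                    stringsAsFactors = FALSE)
  class(out) <- c("hub_table", "data.frame")
  out
}

#' Classify hubs across two groups
#'
#' @param control_hubs region ids that are hubs in the control network.
#' @param patient_hubs region ids that are hubs in the patient network.
#' @return Named character vector over the union: `"lost"` (control only),
#'   `"preserved"` (both), `"reconfigured"` (patient only).
#' @export
classify_hubs <- function(control_hubs, patient_hubs) {
  all_ids <- union(control_hubs, patient_hubs)
  status <- ifelse(all_ids %in% control_hubs & all_ids %in% patient_hubs,
                   "preserved",
                   ifelse(all_ids %in% control_hubs, "lost", "reconfigured"))
  setNames(status, all_ids)
}
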