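# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and igraph) so that agreement is evidence, not tautology.

# brain_network from a 0/1 adjacency or a weight matrix
make_net <- function(m, ids = NULL) {
  m <- as.matrix(m)
  if (is.null(ids)) ids <- paste0("n", seq_len(ncol(m)))
  dimnames(m) <- list(ids, ids)
  brain_network(m, region_ids = ids)
}

# random symmetric 0/1 adjacency
rand_adj <- function(p, prob, seed) {
  set.seed(seed)
  a <- matrix(0, p, p)
  a[upper.tri(a)] <- rbinom(p * (p - 1) / 2, 1, prob)
  a + t(a)
}

# adjacency from a graph index: bits of `code` fill the upper triangle
adj_from_code <- function(p, code) {
  m <- p * (p - 1) / 2
  bits <- as.integer(intToBits(code))[seq_len(m)]
  a <- matrix(0, p, p)
  a[upper.tri(a)] <- bits
  a + t(a)
}

bf_density <- function(adj) {
  p <- nrow(adj)
  sum(adj[upper.tri(adj)]) / (p * (p - 1) / 2)
}

# global clustering: 3 * triangles / connected triples, by exhaustive loops
bf_clustering <- function(adj) {
  p <- nrow(adj)
  triangles <- 0
  triples <- 0
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      for (k in seq_len(p)) {
        if (i < j && j < k) {
          e <- adj[i, j] + adj[j, k] + adj[i, k]
          if (e == 3) triangles <- triangles + 1
        }
      }
    }
    nb <- which(adj[i, ] == 1)
    if (length(nb) >= 2) triples <- triples + choose(length(nb), 2)
  }
  if (triples == 0) 0 else 3 * triangles / triples
}

# all-pairs shortest paths by repeated BFS
bf_distances <- function(adj) {
  p <- nrow(adj)
  d <- matrix(Inf, p, p)
  diag(d) <- 0
  for (s in seq_len(p)) {
    frontier <- s
    dist <- 0
    while (length(frontier) > 0) {
      dist <- dist + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(adj[v, ] == 1)) {
          if (d[s, u] > dist) { d[s, u] <- dist; nxt <- c(nxt, u) }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

bf_avg_path <- function(adj) {
  d <- bf_distances(adj)
  off <- d[upper.tri(d)]
  fin <- is.finite(off)
  list(asp = if (any(fin)) mean(off[fin]) else NaN,
       frac_disc = if (length(off) > 0) mean(!fin) else 0)
}

bf_lcc <- function(adj, nodes) {
  if (length(nodes) == 0) return(0)
  sub <- adj[nodes, nodes, drop = FALSE]
  seen <- rep(FALSE, length(nodes))
  best <- 0
  for (s in seq_along(nodes)) {
    if (seen[s]) next
    comp <- s
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) for (u in which(sub[v, ] == 1)) {
        if (!seen[u]) { seen[u] <- TRUE; nxt <- c(nxt, u); comp <- c(comp, u) }
      }
      frontier <- nxt
    }
    best <- max(best, length(comp))
  }
  best
}

# exact robustness: the expectation over removal orders equals, at each step
# k, the average LCC over all k-subsets removed — enumerate subsets instead
bf_robustness <- function(adj) {
  p <- nrow(adj)
  step_means <- vapply(0:(p - 1), function(k) {
    subs <- utils::combn(p, k)
    if (k == 0) return(bf_lcc(adj, seq_len(p)) / p)
    mean(apply(subs, 2, function(rm) bf_lcc(adj, setdiff(seq_len(p), rm)) / p))
  }, numeric(1))
  mean(step_means)
}

bf_participation <- function(w, membership) {
  w <- abs(w)
  p <- nrow(w)
  out <- numeric(p)
  for (i in seq_len(p)) {
    k <- sum(w[i, ])
    if (k == 0) { out[i] <- 0; next }
    acc <- 0
    for (s in unique(membership)) {
      acc <- acc + (sum(w[i, membership == s]) / k)^2
    }
    out[i] <- 1 - acc
  }
  out
}

# Newman weighted modularity at resolution 1
bf_modularity <- function(w, membership) {
  w <- abs(w)
  diag(w) <- 0
  m2 <- sum(w)
  if (m2 == 0) return(0)
  k <- rowSums(w)
  q <- 0
  p <- nrow(w)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (membership[i] == membership[j]) q <- q + w[i, j] - k[i] * k[j] / m2
  }
  q / m2
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) { out[[length(out) + 1]] <<- prefix; return() }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0)
  out
}

bf_max_modularity <- function(w) {
  parts <- all_partitions(nrow(w))
  max(vapply(parts, function(m) bf_modularity(w, m), numeric(1)))
}

# pairwise Mann-Whitney AUC with 1/2 tie credit
bf_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cases) * length(controls))
}

bf_delong_var <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  m <- length(cases); n <- length(controls)
  v10 <- numeric(m); v01 <- numeric(n)
  for (i in seq_len(m)) {
    acc <- 0
    for (j in seq_len(n)) {
      acc <- acc + if (cases[i] > controls[j]) 1 else
        if (cases[i] == controls[j]) 0.5 else 0
    }
    v10[i] <- acc / n
  }
  for (j in seq_len(n)) {
    acc <- 0
    for (i in seq_len(m)) {
      acc <- acc + if (cases[i] > controls[j]) 1 else
        if (cases[i] == controls[j]) 0.5 else 0
    }
    v01[j] <- acc / m
  }
  var(v10) / m + var(v01) / n
}

# small simulated study shared by several test files
quick_sim <- function(p = 10, n = c(CTRL = 20, nTRS = 20, TRS = 20),
                      attenuation = 0.4, r = 0.3, seed = 1,
                      scale_sd = 0.1, confounder = list(enabled = FALSE)) {
  atlas <- synthetic_atlas(p)
  cfg <- simulation_config(n_per_group = n, p = p,
                           within_module_partial = r,
                           patient_edge_attenuation = attenuation,
                           global_scale_sd = scale_sd,
                           dose_confounder = confounder, seed = seed)
  specs <- lapply(setNames(nm = names(n)), function(g) {
    build_ground_truth_precision(atlas, cfg, g)
  })
  c(simulate_study(specs, cfg), list(atlas = atlas, config = cfg))
}
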