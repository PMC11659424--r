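test_that("closed-form graphs: complete, triangle, path", {
  # K5: density 1, clustering 1, mean distance 1, robustness (N+1)/(2N) = 0.6
  k5 <- make_net(matrix(1, 5, 5) - diag(5))
  s <- summarize_graph(k5, n_ref = 5, n_orders = 200, seed = 1)
  expect_equal(s$n_edges, 10)
  expect_equal(s$edge_density, 1)
  expect_equal(s$global_clustering, 1)
  expect_equal(s$avg_shortest_path, 1)
  expect_equal(s$frac_disconnected_pairs, 0)
  expect_equal(s$robustness, 0.6)   # 5! = 120 <= 200: exact enumeration

  # complete-graph robustness closed form for several sizes
  for (N in c(3, 5)) {
    kn <- make_net(matrix(1, N, N) - diag(N))
    s <- summarize_graph(kn, n_ref = 2, n_orders = factorial(N), seed = 1)
    expect_equal(s$robustness, (N + 1) / (2 * N))
  }

  # triangle: all triples closed
  tri <- make_net(adj_from_code(3, 7))
  expect_equal(summarize_graph(tri, n_ref = 2, n_orders = 6, seed = 1)$global_clustering, 1)

  # 3-node path A-B-C: distances 1, 1, 2
  pth <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  s <- summarize_graph(make_net(pth), n_ref = 2, n_orders = 6, seed = 1)
  expect_equal(s$avg_shortest_path, 4 / 3)
  expect_equal(s$global_clustering, 0)
})

test_that("edgeless graphs degrade to sentinels", {
  s <- summarize_graph(make_net(matrix(0, 4, 4)), n_ref = 2, n_orders = 24, seed = 1)
  expect_equal(s$n_edges, 0)
  expect_equal(s$edge_density, 0)
  expect_equal(s$global_clustering, 0)
  expect_true(is.nan(s$avg_shortest_path))
  expect_true(is.nan(s$small_worldness))
  expect_equal(s$frac_disconnected_pairs, 1)
  expect_true(s$degenerate)
})

test_that("metrics equal exhaustive brute force on small graphs", {
  # all 64 graphs on 4 nodes, plus a deterministic sample of 5-node graphs
  codes5 <- c(0, 1, 5, 37, 100, 341, 512, 682, 767, 1023,
              round(seq(7, 1015, length.out = 30)))
  cases <- c(lapply(0:63, function(cd) adj_from_code(4, cd)),
             lapply(codes5, function(cd) adj_from_code(5, cd)))
  for (adj in cases) {
    net <- make_net(adj)
    s <- summarize_graph(net, n_ref = 0, n_orders = factorial(nrow(adj)), seed = 1)
    expect_equal(s$edge_density, bf_density(adj))
    expect_equal(s$global_clustering, bf_clustering(adj))
    o <- bf_avg_path(adj)
    if (is.nan(o$asp)) expect_true(is.nan(s$avg_shortest_path)) else
      expect_equal(s$avg_shortest_path, o$asp)
    expect_equal(s$frac_disconnected_pairs, o$frac_disc)
    expect_equal(s$robustness, bf_robustness(adj), tolerance = 1e-12)
  }
})

test_that("weighted degree sums absolute incident weights", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.3
  w[2, 3] <- w[3, 2] <- -0.2
  net <- make_net(w)
  d <- weighted_degree(net)
  expect_equal(unname(d), c(0.3, 0.5, 0.2))
  # handshake identity on random weighted graphs
  for (s in 1:5) {
    set.seed(s)
    ww <- matrix(0, 8, 8)
    ww[upper.tri(ww)] <- rnorm(28) * rbinom(28, 1, 0.4)
    ww <- ww + t(ww)
    net <- make_net(ww)
    expect_equal(sum(weighted_degree(net)), 2 * sum(abs(ww[upper.tri(ww)])))
  }
  # isolated node
  expect_equal(unname(weighted_degree(make_net(matrix(0, 2, 2)))), c(0, 0))
})

test_that("louvain partition maximizes modularity on canonical cases", {
  # two disjoint triangles: optimum splits them
  adj <- matrix(0, 6, 6)
  adj[1:3, 1:3] <- 1; adj[4:6, 4:6] <- 1; diag(adj) <- 0
  net <- make_net(adj)
  part <- louvain_partition(net, seed = 1)
  m <- part$assignment
  expect_equal(length(unique(m)), 2)
  expect_equal(length(unique(m[1:3])), 1)
  expect_equal(length(unique(m[4:6])), 1)
  expect_equal(bf_modularity(adj, m), bf_max_modularity(adj), tolerance = 1e-12)

  # complete graph: one community is optimal
  k5 <- matrix(1, 5, 5) - diag(5)
  part <- louvain_partition(make_net(k5), seed = 1)
  expect_equal(length(unique(part$assignment)), 1)
  expect_gte(bf_modularity(k5, part$assignment) + 1e-12, bf_max_modularity(k5))

  # determinism and contiguous 0-based indexing
  p1 <- louvain_partition(net, seed = 7)
  p2 <- louvain_partition(net, seed = 7)
  expect_identical(p1$assignment, p2$assignment)
  expect_setequal(unique(p1$assignment), seq_along(unique(p1$assignment)) - 1L)

  # edgeless graph: singleton communities
  p0 <- louvain_partition(make_net(matrix(0, 4, 4)))
  expect_equal(sort(unname(p0$assignment)), 0:3)
})

test_that("community average degree is the within-community density", {
  adj <- matrix(0, 6, 6)
  adj[1:3, 1:3] <- 1                      # complete triangle
  diag(adj) <- 0                          # nodes 4:6 isolated
  net <- make_net(adj)
  grouping <- setNames(c(1, 1, 1, 2, 2, 2), paste0("n", 1:6))
  cad <- community_average_degree(net, grouping)
  expect_equal(unname(cad["1"]), 1.0)
  expect_equal(unname(cad["2"]), 0.0)
  # singleton community warns and returns 0
  g2 <- setNames(c(1, 1, 1, 2, 2, 3), paste0("n", 1:6))
  expect_warning(cad2 <- community_average_degree(net, g2), "singleton")
  expect_equal(unname(cad2["3"]), 0)
  # subnetwork mode: labels covering a subset restrict to it
  sub <- setNames(c(1, 1, 1), paste0("n", 1:3))
  expect_equal(unname(community_average_degree(net, sub)), 1.0)
})

test_that("implanted subnetwork density is recovered from estimated nets", {
  # 8 DMN regions with 21/28 within-DMN edges (density 0.75) in the truth;
  # estimate at large n and read the within-DMN average degree back
  set.seed(42)
  p <- 14
  ids <- sprintf("region_%03d", 1:p)
  theta <- diag(p)
  dmn_pairs <- which(upper.tri(matrix(0, 8, 8)), arr.ind = TRUE)
  keep <- sample(nrow(dmn_pairs), 21)
  for (k in keep) theta[dmn_pairs[k, 1], dmn_pairs[k, 2]] <- -0.3
  theta[9, 10] <- theta[11, 12] <- theta[13, 14] <- -0.3
  theta <- theta + t(theta) - diag(diag(theta))
  diag(theta) <- pmax(1, 1.05 * (rowSums(abs(theta)) - diag(theta)))
  x <- MASS::mvrnorm(5000, rep(0, p), solve(theta))
  colnames(x) <- ids
  fit <- select_lambda_bic(cor(x), 5000)
  w <- fit$partial; diag(w) <- 0
  net <- brain_network(w, region_ids = ids)
  cad <- community_average_degree(net, setNames(rep("dmn", 8), ids[1:8]))
  expect_equal(unname(cad["dmn"]), 0.75, tolerance = 0.07)
})

test_that("participation coefficients follow the spread formula", {
  # all connections inside own community -> 0
  adj <- matrix(0, 6, 6); adj[1:3, 1:3] <- 1; adj[4:6, 4:6] <- 1; diag(adj) <- 0
  net <- make_net(adj)
  part <- louvain_partition(net, seed = 1)
  pc <- participation_coefficients(net, part)
  expect_equal(unname(pc), rep(0, 6))

  # strength split evenly across 2 communities -> 0.5; s communities -> 1 - 1/s
  star <- matrix(0, 9, 9)
  star[1, 2:9] <- 1; star[2:9, 1] <- 1
  net <- make_net(star)
  member <- setNames(c(1, rep(1:4, each = 2)), paste0("n", 1:9))
  pc <- participation_coefficients(net, member)
  # hub connects 2 nodes in each of 4 communities: P = 1 - 4*(2/8)^2 = 0.75
  expect_equal(unname(pc["n1"]), 1 - 1 / 4)
  member2 <- setNames(c(1, rep(1:2, each = 4)), paste0("n", 1:9))
  expect_equal(unname(participation_coefficients(net, member2)["n1"]), 0.5)

  # matches brute force on random weighted graphs, bounded by 1 - 1/s
  for (s in 1:5) {
    set.seed(s)
    ww <- matrix(0, 10, 10)
    ww[upper.tri(ww)] <- rnorm(45) * rbinom(45, 1, 0.5)
    ww <- ww + t(ww)
    net <- make_net(ww)
    part <- louvain_partition(net, seed = s)
    pc <- participation_coefficients(net, part)
    expect_equal(unname(pc), bf_participation(ww, part$assignment), tolerance = 1e-12)
    ns <- length(unique(part$assignment))
    expect_true(all(pc <= 1 - 1 / ns + 1e-12))
    expect_true(all(pc >= 0))
  }
})

test_that("hub rule: one sd above the mean participation", {
  pc <- setNames(c(0, 0, 0, 1), paste0("n", 1:4))
  tab <- identify_hubs(pc)
  expect_s3_class(tab, "hub_table")
  # mean 0.25, sd 0.5, threshold 0.75: only the fourth node
  expect_identical(tab$region_id[tab$is_hub], "n4")
  # constant vector: strict inequality, no hubs
  expect_false(any(identify_hubs(setNames(rep(0.4, 5), paste0("n", 1:5)))$is_hub))
  # single extreme outlier among 64 zeros
  pc2 <- setNames(c(rep(0, 64), 0.9), paste0("r", 1:65))
  hubs <- identify_hubs(pc2)
  expect_identical(hubs$region_id[hubs$is_hub], "r65")
  expect_error(identify_hubs(c(a = 1)), "at least 2")
})

test_that("hub status classification is plain set algebra", {
  st <- classify_hubs(c("a", "b"), c("b", "c"))
  expect_equal(st[["a"]], "lost")
  expect_equal(st[["b"]], "preserved")
  expect_equal(st[["c"]], "reconfigured")
  expect_true(all(classify_hubs(c("x", "y"), c("x", "y")) == "preserved"))
  expect_false("preserved" %in% classify_hubs("x", "y"))
  expect_length(classify_hubs(character(0), character(0)), 0)
})

test_that("metrics are invariant to node relabeling", {
  set.seed(11)
  adj <- rand_adj(9, 0.35, 11)
  net1 <- make_net(adj)
  perm <- sample(9)
  net2 <- make_net(adj[perm, perm])
  for (f in list(
    function(n) summarize_graph(n, n_ref = 0, n_orders = 5000, seed = 3)$global_clustering,
    function(n) summarize_graph(n, n_ref = 0, n_orders = 5000, seed = 3)$avg_shortest_path,
    function(n) summarize_graph(n, n_ref = 0, n_orders = 5000, seed = 3)$edge_density,
    function(n) sort(unname(weighted_degree(n))))) {
    expect_equal(f(net1), f(net2), tolerance = 1e-12)
  }
  # robustness is sampled, so compare with Monte-Carlo tolerance
  r1 <- summarize_graph(net1, n_ref = 0, n_orders = 3000, seed = 5)$robustness
  r2 <- summarize_graph(net2, n_ref = 0, n_orders = 3000, seed = 6)$robustness
  expect_equal(r1, r2, tolerance = 0.02)
})

test_that("small-worldness of random graphs is near 1", {
  sw <- numeric(8)
  for (s in seq_along(sw)) {
    adj <- rand_adj(50, 0.2, 100 + s)
    net <- make_net(adj)
    sm <- summarize_graph(net, n_ref = 20, n_orders = 50, seed = s)
    sw[s] <- sm$small_worldness
  }
  expect_gt(mean(sw), 0.8)
  expect_lt(mean(sw), 1.2)
})
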