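test_that("characteristic path length matches hand-enumerated graphs", {
  expect_equal(as.numeric(characteristic_path_length(as_net(adj_complete(6)))), 1)
  expect_equal(as.numeric(characteristic_path_length(as_net(adj_path(3)))), 4 / 3)
  expect_equal(as.numeric(characteristic_path_length(as_net(adj_star(4)))), 8 / 5)
})

test_that("unreachable pairs are excluded and counted", {
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1L  # two K2 components
  cpl <- characteristic_path_length(as_net(A))
  expect_equal(as.numeric(cpl), 1)
  expect_equal(attr(cpl, "n_unreachable"), 8L)
  expect_error(characteristic_path_length(as_net(matrix(0L, 3, 3))),
               "no reachable")
})

test_that("clustering coefficient matches triangle counting", {
  expect_equal(clustering_coefficient(as_net(adj_complete(3))), 1)
  expect_equal(clustering_coefficient(as_net(adj_star(4))), 0)
  A <- adj_complete(4)
  A[1, 2] <- A[2, 1] <- 0L  # K4 minus one edge
  cc <- clustering_coefficient(as_net(A), nodal = TRUE)
  expect_equal(unname(cc), c(1, 1, 2 / 3, 2 / 3))
  expect_equal(clustering_coefficient(as_net(A)), 5 / 6)
})

test_that("global efficiency matches pair enumeration", {
  expect_equal(global_efficiency(as_net(adj_complete(5))), 1)
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1L
  expect_equal(global_efficiency(as_net(A)), 1 / 3)
  expect_equal(global_efficiency(as_net(adj_path(3))), 5 / 6)
})

test_that("local efficiency matches induced-subgraph enumeration", {
  expect_equal(local_efficiency(as_net(adj_complete(4))), 1)
  expect_equal(local_efficiency(as_net(adj_star(4))), 0)
  A <- matrix(0L, 4, 4)   # triangle 1-2-3 plus pendant 4 on node 1
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- A[1, 3] <- A[3, 1] <- 1L
  A[1, 4] <- A[4, 1] <- 1L
  le <- local_efficiency(as_net(A), nodal = TRUE)
  expect_equal(unname(le), bf_local_eff_nodal(A))
})

test_that("betweenness matches known hubs and normalization", {
  b_star <- betweenness_centrality(as_net(adj_star(4)), nodal = TRUE)
  expect_equal(unname(b_star[1]), 1)       # hub carries all 6 leaf pairs
  expect_equal(unname(b_star[2]), 0)       # leaves lie on no paths
  b_path <- betweenness_centrality(as_net(adj_path(3)), nodal = TRUE)
  expect_equal(unname(b_path[2]), 1)
})

test_that("assortativity matches the edge-list correlation", {
  expect_equal(assortativity_coefficient(as_net(adj_star(3))), -1)
  expect_warning(r <- assortativity_coefficient(as_net(adj_complete(4))),
                 "no degree variance")
  expect_true(is.na(r))
  # two K3's joined by a bridge
  A <- matrix(0L, 6, 6)
  A[1:3, 1:3] <- adj_complete(3)
  A[4:6, 4:6] <- adj_complete(3)
  A[3, 4] <- A[4, 3] <- 1L
  expect_equal(assortativity_coefficient(as_net(A)), bf_assortativity(A),
               tolerance = 1e-12)
})

test_that("modularity recovers planted structure and known values", {
  A <- matrix(0L, 8, 8)
  A[1:4, 1:4] <- adj_complete(4)
  A[5:8, 5:8] <- adj_complete(4)
  res <- graph_modularity(as_net(A), seed = 1)
  expect_equal(res$Q, 0.5)
  expect_equal(length(unique(res$membership[1:4])), 1L)
  expect_equal(length(unique(res$membership[5:8])), 1L)
  res_k <- graph_modularity(as_net(adj_complete(6)), seed = 1)
  expect_equal(res_k$Q, 0)
  expect_equal(length(unique(res_k$membership)), 1L)
  expect_error(graph_modularity(as_net(matrix(0L, 3, 3))), "edge")
})

test_that("modularity is deterministic given its seed", {
  A <- rand_adj(30, 0.15, 11)
  r1 <- graph_modularity(as_net(A), seed = 9)
  r2 <- graph_modularity(as_net(A), seed = 9)
  expect_identical(r1, r2)
})

test_that("planted two-block graphs are recovered in nearly all seeds", {
  hits <- 0L
  n_seeds <- 40L
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    A <- matrix(0L, 40, 40)
    ut <- which(upper.tri(A))
    same <- outer(rep(1:2, each = 20), rep(1:2, each = 20), "==")[ut]
    A[ut] <- rbinom(length(ut), 1L, ifelse(same, 0.9, 0.05))
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    res <- graph_modularity(as_net(A), seed = s)
    m <- res$membership
    agree <- length(unique(m[1:20])) == 1L &&
      length(unique(m[21:40])) == 1L && m[1] != m[21]
    hits <- hits + agree
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("all metrics are invariant under node relabeling", {
  set.seed(21)
  A <- rand_adj(12, 0.3, 21)
  perm <- sample(12)
  P <- A[perm, perm]
  n1 <- as_net(A)
  n2 <- as_net(P)
  expect_equal(as.numeric(characteristic_path_length(n1)),
               as.numeric(characteristic_path_length(n2)))
  expect_equal(clustering_coefficient(n1), clustering_coefficient(n2))
  expect_equal(global_efficiency(n1), global_efficiency(n2))
  expect_equal(local_efficiency(n1), local_efficiency(n2))
  expect_equal(betweenness_centrality(n1), betweenness_centrality(n2))
  expect_equal(assortativity_coefficient(n1), assortativity_coefficient(n2),
               tolerance = 1e-12)
})

test_that("path length and efficiency are consistent with one distance oracle", {
  for (s in 1:20) {
    A <- rand_adj(10, 0.35, 100 + s)
    if (sum(A) == 0) next
    net <- as_net(A)
    expect_equal(as.numeric(characteristic_path_length(net)), bf_cpl(A),
                 tolerance = 1e-12)
    expect_equal(global_efficiency(net), bf_geff(A), tolerance = 1e-12)
  }
})

test_that("lobar averages aggregate nodal values correctly", {
  lm <- aal90_lobe_map()
  regions <- lm$region
  const <- setNames(rep(3.3, 90), regions)
  out <- lobar_average(const, lm)
  expect_equal(nrow(out), 10L)
  expect_true(all(abs(out$value - 3.3) < 1e-12))
  onehot <- setNames(rep(0, 90), regions)
  onehot["Precuneus_L"] <- 1
  out1 <- lobar_average(onehot, lm)
  cell <- out1[out1$lobe == "parietal" & out1$hemisphere == "L", "value"]
  n_cell <- sum(lm$lobe == "parietal" & lm$hemisphere == "L")
  expect_equal(cell, 1 / n_cell)
  expect_true(all(out1$value[!(out1$lobe == "parietal" &
                                 out1$hemisphere == "L")] == 0))
  set.seed(31)
  vals <- setNames(rnorm(90), regions)
  out2 <- lobar_average(vals, lm)
  oracle <- tapply(vals, paste(lm$lobe, lm$hemisphere), mean)
  expect_equal(out2$value, as.numeric(oracle[paste(out2$lobe, out2$hemisphere)]))
  bad <- setNames(1:3, c("Precuneus_L", "nowhere", "Precuneus_R"))
  expect_error(lobar_average(bad, lm), "nowhere")
})

test_that("network_metrics bundles globals, nodal table and lobar table", {
  set.seed(41)
  spec <- cohort_spec(group_sizes = c(HS = 1L), coupling_by_group = c(HS = 0.6))
  s <- generate_subject(spec, "HS", 1)
  net <- threshold_to_density(build_mi_matrix(s$ts), 0.07)
  m <- network_metrics(net, lobe_map = aal90_lobe_map(), seed = 2)
  expect_named(m$global, c("char_path_length", "clustering_coeff",
                           "global_efficiency", "local_efficiency",
                           "betweenness_mean", "assortativity", "modularity"))
  expect_equal(nrow(m$nodal), 90L)
  expect_equal(nrow(m$lobar), 10L)
  expect_true(m$global["global_efficiency"] <= 1)
  expect_true(all(m$nodal$betweenness >= 0))
})
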