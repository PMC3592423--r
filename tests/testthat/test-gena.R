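chain_net <- function(w = c(0.3, 0.5, 0.2, 0.4))
  gene_network(data.frame(from = paste0("n", 1:4), to = paste0("n", 2:5),
                          weight = w))

test_that("transition matrix is MI-proportional and row-stochastic", {
  single <- gene_network(data.frame(from = "a", to = "b", weight = 0.7))
  tm <- transition_matrix(single)
  expect_equal(tm$W["a", "b"], 1)
  expect_equal(tm$W["b", "a"], 1)

  two <- gene_network(data.frame(from = c("x", "x"), to = c("y", "z"),
                                 weight = c(0.2, 0.6)))
  tm2 <- transition_matrix(two)
  expect_equal(unname(tm2$W["x", c("y", "z")]), c(0.25, 0.75))

  for (s in 1:5) {
    net <- random_network(20, p_edge = 0.2, seed = 500 + s)
    tm <- transition_matrix(net)
    rs <- rowSums(tm$W)
    expect_lt(max(abs(rs[!tm$dangling] - 1)), 1e-12)
    expect_true(all(rs[tm$dangling] == 0))
    # positive transition weight only on network edges
    ekey <- c(paste(net$edges$from, net$edges$to),
              paste(net$edges$to, net$edges$from))
    wkey <- which(tm$W > 0, arr.ind = TRUE)
    expect_true(all(paste(rownames(tm$W)[wkey[, 1]],
                          colnames(tm$W)[wkey[, 2]]) %in% ekey))
  }
})

test_that("restart-only walk returns the preference vector", {
  net <- chain_net()
  tm <- transition_matrix(net)
  R <- rank_genes(tm, seeds = c("n1", "n3"), restart = 1)
  expect_equal(unname(R[c("n1", "n3")]), c(0.5, 0.5))
  expect_equal(sum(R), 1)
  expect_equal(unname(R[c("n2", "n4", "n5")]), c(0, 0, 0))
})

test_that("iterative ranking equals a dense linear solve", {
  for (s in 1:6) {
    n <- sample(10:50, 1)
    net <- random_network(n, p_edge = 0.15, seed = 600 + s)
    tm <- transition_matrix(net)
    if (any(tm$dangling)) next  # solver oracle assumes no dangling nodes
    seeds <- sample(net$nodes, 2)
    r <- 0.3
    R <- rank_genes(tm, seeds, restart = r)
    P <- setNames(numeric(n), tm$nodes); P[seeds] <- 0.5
    oracle <- solve(diag(n) - (1 - r) * t(tm$W), r * P)
    expect_lt(max(abs(R - oracle)), 1e-8)
    expect_equal(sum(R), 1, tolerance = 1e-12)
  }
  # 5-node chain, single seed, explicit solve
  net <- chain_net()
  tm <- transition_matrix(net)
  R <- rank_genes(tm, "n1", restart = 0.3)
  P <- setNames(c(1, 0, 0, 0, 0), paste0("n", 1:5))
  oracle <- solve(diag(5) - 0.7 * t(tm$W), 0.3 * P)
  expect_lt(max(abs(R[names(P)] - oracle)), 1e-8)
})

test_that("rank mass is conserved and symmetry is respected", {
  # symmetric 4-cycle with symmetric seeds gives symmetric ranks
  net <- gene_network(data.frame(from = c("a", "b", "c", "d"),
                                 to = c("b", "c", "d", "a"), weight = 1))
  R <- rank_genes(transition_matrix(net), seeds = c("a", "c"), restart = 0.4)
  expect_equal(unname(R["a"]), unname(R["c"]), tolerance = 1e-12)
  expect_equal(unname(R["b"]), unname(R["d"]), tolerance = 1e-12)
  expect_equal(sum(R), 1, tolerance = 1e-12)
})

test_that("rank decays monotonically with distance from a path-end seed", {
  net <- gene_network(data.frame(from = paste0("p", 1:7),
                                 to = paste0("p", 2:8), weight = 1))
  R <- rank_genes(transition_matrix(net), "p1", restart = 0.3)
  expect_true(all(diff(R[paste0("p", 1:8)]) < 0))
})

test_that("dangling mass is redirected (or rejected in strict mode)", {
  net <- gene_network(data.frame(from = "a", to = "b", weight = 1),
                      nodes = c("a", "b", "lonely"))
  tm <- transition_matrix(net)
  R <- rank_genes(tm, "a", restart = 0.3)
  expect_equal(sum(R), 1, tolerance = 1e-12)
  expect_equal(unname(R["lonely"]), 0)
  expect_error(rank_genes(tm, "a", restart = 0.3, dangling = "error"),
               "edge-less")
})

test_that("convergence failure reports the residual", {
  net <- chain_net()
  tm <- transition_matrix(net)
  expect_error(rank_genes(tm, "n1", restart = 0.05, max_iter = 2),
               "did not converge")
})

test_that("subnetwork growth stops at first connectivity", {
  # seeds already connected: zero genes added
  net <- chain_net()
  sub0 <- extract_subnetwork(net, c("n2", "n3"))
  expect_equal(nrow(sub0$added), 0L)
  expect_setequal(sub0$nodes, c("n2", "n3"))

  # two seeds joined only via x (an unreachable component carries no rank):
  # exactly {x} is added, whatever its rank
  bridge <- gene_network(data.frame(
    from = c("s1", "x", "a", "b"),
    to = c("x", "s2", "b", "c"),
    weight = c(0.1, 0.1, 0.9, 0.9)))
  sub <- extract_subnetwork(bridge, c("s1", "s2"))
  expect_identical(sub$added$gene, "x")
  # a decoy reachable from a seed may be picked up on the way if it
  # outranks the bridge, but growth still stops at first connectivity
  decoy <- gene_network(data.frame(
    from = c("s1", "x", "s1", "a", "b"),
    to = c("x", "s2", "a", "b", "c"),
    weight = c(0.1, 0.1, 0.9, 0.9, 0.9)))
  sub2 <- extract_subnetwork(decoy, c("s1", "s2"))
  expect_true("x" %in% sub2$added$gene)
  expect_identical(utils::tail(sub2$added$gene, 1), "x")

  # result is connected and contains all seeds
  for (s in 1:5) {
    net <- random_network(25, p_edge = 0.12, seed = 700 + s)
    tm <- transition_matrix(net)
    seeds <- sample(net$nodes[!tm$dangling], 3)
    sub <- try(extract_subnetwork(net, seeds, restart = 0.3), silent = TRUE)
    if (inherits(sub, "try-error")) next  # seeds in unreachable components
    expect_true(all(seeds %in% sub$nodes))
    g <- igraph::graph_from_data_frame(sub$edges, directed = FALSE,
                                       vertices = sub$nodes)
    expect_equal(igraph::components(g)$no, 1L)
  }
})

test_that("unreachable seeds raise after candidate exhaustion", {
  two_islands <- gene_network(data.frame(from = c("a", "c"),
                                         to = c("b", "d"), weight = 1))
  expect_error(extract_subnetwork(two_islands, c("a", "c")),
               "cannot be connected")
})

test_that("rank ties break lexicographically and reruns are identical", {
  # two symmetric bridges y/z between the seeds: equal ranks, y added first
  net <- gene_network(data.frame(from = c("s1", "s1", "z", "y"),
                                 to = c("z", "y", "s2", "s2"),
                                 weight = 0.5))
  sub1 <- extract_subnetwork(net, c("s1", "s2"))
  sub2 <- extract_subnetwork(net, c("s1", "s2"))
  expect_identical(sub1$added, sub2$added)
  expect_identical(sub1$added$gene[1], "y")
})

test_that("seed files parse with comments", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# seeds", "g1", "", "g2", "g1"), f)
  expect_equal(read_seeds(f), c("g1", "g2"))
})
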