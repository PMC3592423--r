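test_that("topology sampling is reproducible, connected and size-accurate", {
  t1 <- sample_topology(10, seed = 5)
  t2 <- sample_topology(10, seed = 5)
  expect_identical(t1, t2)
  expect_error(sample_topology(5), ">= 10")

  tt <- sample_topology(200, avg_degree = 2, seed = 8)
  expect_lt(abs(nrow(tt) - 200 * 2 / 2) / (200 * 2 / 2), 0.2)
  g <- igraph::graph_from_data_frame(tt, directed = TRUE)
  expect_true(igraph::is_connected(g, mode = "weak"))
  # regulator -> target edges follow node order: acyclic
  expect_true(igraph::is_dag(g))
})

test_that("preferential-attachment degrees decay like a power law", {
  tt <- sample_topology(2000, avg_degree = 2, seed = 13)
  deg <- table(c(tt$regulator, tt$target))
  all_deg <- setNames(integer(2000), attr(tt, "genes"))
  all_deg[names(deg)] <- as.integer(deg)
  fit <- powerlaw_fit(as.numeric(all_deg), k_min = 1)
  expect_false(fit$flat)
  # cumulative-variant slope is the robust estimate on empirical graphs
  expect_gte(fit$gamma_cum, 2)
  expect_lte(fit$gamma_cum, 3)
})

test_that("expression simulation follows the truth network", {
  # noise-free linear chain: child exactly +/- parent
  chain <- structure(data.frame(regulator = c("G0001", "G0002"),
                                target = c("G0002", "G0003")),
                     genes = c("G0001", "G0002", "G0003"),
                     class = c("truth_network", "data.frame"))
  x <- simulate_expression(chain, "linear", m = 20, noise_sd = 0,
                           seed = 3)$values
  expect_equal(abs(cor(x["G0001", ], x["G0002", ])), 1, tolerance = 1e-12)
  expect_equal(abs(cor(x["G0002", ], x["G0003", ])), 1, tolerance = 1e-12)

  # bit-identical under a fixed seed
  tt <- sample_topology(30, seed = 21)
  a <- simulate_expression(tt, "sigmoidal", m = 15, seed = 9)
  b <- simulate_expression(tt, "sigmoidal", m = 15, seed = 9)
  expect_identical(a$values, b$values)

  # two independent roots decorrelate as m grows
  roots <- structure(data.frame(regulator = "G0001", target = "G0003"),
                     genes = c("G0001", "G0002", "G0003"),
                     class = c("truth_network", "data.frame"))
  big <- simulate_expression(roots, "linear", m = 5000, noise_sd = 0,
                             seed = 4)$values
  expect_lt(abs(cor(big["G0001", ], big["G0002", ])), 3 / sqrt(5000))

  # cyclic truths iterate by default, error in strict mode
  cyc <- structure(data.frame(regulator = c("G0001", "G0002"),
                              target = c("G0002", "G0001")),
                   genes = c("G0001", "G0002"),
                   class = c("truth_network", "data.frame"))
  expect_error(simulate_expression(cyc, "linear", m = 10, cyclic = "error"),
               "cyclic")
  expect_silent(x <- simulate_expression(cyc, "linear", m = 10, seed = 2))
})

test_that("prediction scoring matches the confusion-matrix oracle", {
  nodes <- paste0("G", 1:5)
  truth <- structure(data.frame(regulator = c("G1", "G2", "G3"),
                                target = c("G2", "G3", "G4")),
                     genes = nodes, class = c("truth_network", "data.frame"))
  # perfect prediction
  perfect <- gene_network(data.frame(from = truth$regulator,
                                     to = truth$target, weight = 1),
                          nodes = nodes)
  sp <- score_prediction(perfect, truth)
  expect_equal(c(sp$precision, sp$recall, sp$fscore), c(1, 1, 1))
  expect_equal(sp$auroc, 1)
  expect_equal(sp$aupr, 1)

  # disjoint prediction
  disjoint <- gene_network(data.frame(from = c("G1", "G2"), to = c("G5", "G5"),
                                      weight = 1), nodes = nodes)
  sd_ <- score_prediction(disjoint, truth)
  expect_equal(c(sd_$precision, sd_$recall, sd_$fscore), c(0, 0, 0))

  # 2 of 3 true edges among 4 predictions: p = 1/2, r = 2/3, F = 4/7
  four <- gene_network(data.frame(from = c("G1", "G2", "G1", "G4"),
                                  to = c("G2", "G3", "G5", "G5"), weight = 1),
                       nodes = nodes)
  sf <- score_prediction(four, truth)
  expect_equal(sf$precision, 0.5)
  expect_equal(sf$recall, 2 / 3)
  expect_equal(sf$fscore, 4 / 7)

  expect_error(score_prediction(perfect, truth[0, ]), "empty truth")

  # random small cases against the oracle
  set.seed(60)
  for (rep in 1:20) {
    nn <- sample(4:8, 1)
    nd <- paste0("N", seq_len(nn))
    pairs <- t(combn(nd, 2))
    tsel <- runif(nrow(pairs)) < 0.4
    psel <- runif(nrow(pairs)) < 0.4
    if (!any(tsel)) next
    tr <- structure(data.frame(regulator = pairs[tsel, 1],
                               target = pairs[tsel, 2]),
                    genes = nd, class = c("truth_network", "data.frame"))
    pr <- gene_network(
      if (any(psel)) data.frame(from = pairs[psel, 1], to = pairs[psel, 2],
                                weight = runif(sum(psel))) else NULL,
      nodes = nd)
    got <- score_prediction(pr, tr, curves = FALSE)
    want <- oracle_score(pr$edges, tr[, 1:2], nd)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$fscore, want$fscore)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(61)
  labels <- c(rep(1, 15), rep(0, 85))
  score <- rnorm(100) + labels
  score[1:30] <- round(score[1:30], 1)  # induce some ties
  cur <- splinenet:::ranked_curves(score, labels == 1)
  ref <- suppressMessages(as.numeric(pROC::auc(labels, score)))
  expect_equal(cur$auroc, ref, tolerance = 1e-12)
})

test_that("gold-standard reader keeps only indicator-1 edges", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("G1\tG2\t1", "G1\tG3\t0", "G2\tG3\t1"), f)
  g <- read_gold_standard(f)
  expect_equal(nrow(g), 2L)
  expect_setequal(g$regulator, c("G1", "G2"))
})

test_that("challenge-style scoring separates perfect from random", {
  set.seed(62)
  nodes <- paste0("G", 1:12)
  pairs <- t(combn(nodes, 2))
  tsel <- runif(nrow(pairs)) < 0.25
  truth <- structure(data.frame(regulator = pairs[tsel, 1],
                                target = pairs[tsel, 2]),
                     genes = nodes, class = c("truth_network", "data.frame"))
  perfect <- gene_network(data.frame(from = truth$regulator,
                                     to = truth$target,
                                     weight = seq_len(nrow(truth)) + 1),
                          nodes = nodes)
  rand <- gene_network(data.frame(from = pairs[, 1], to = pairs[, 2],
                                  weight = runif(nrow(pairs))), nodes = nodes)
  sc <- dream_score(list(perfect, rand), list(truth, truth),
                    n_null = 100, seed = 9)
  expect_gt(sc$p_aupr[2], sc$p_aupr[1])
  expect_gt(sc$score, 0)
  expect_equal(sc$p_auroc[1], 1 / 101)  # perfect beats every null draw
})

test_that("benchmark runs reproducibly and beats the random baseline", {
  res1 <- run_benchmark(n = 30, m = 60, type = "linear", reps = 2,
                        noise_sd = 0.05, bins = 6, epsilon = 0.01,
                        n_perm = 1000, seed = 77)
  res2 <- run_benchmark(n = 30, m = 60, type = "linear", reps = 2,
                        noise_sd = 0.05, bins = 6, epsilon = 0.01,
                        n_perm = 1000, seed = 77)
  expect_identical(res1, res2)
  expect_gt(attr(res1, "mean_f"), mean(res1$f_random))
  expect_true(all(res1$fscore >= 0 & res1$fscore <= 1))
})
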