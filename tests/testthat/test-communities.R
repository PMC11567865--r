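two_cliques <- function(w_between = -0.3) {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 0.3
  W[5:8, 5:8] <- 0.3
  diag(W) <- 0
  W[4, 5] <- W[5, 4] <- w_between
  signed_network(W, sprintf("n%d", 1:8))
}

planted_blocks <- function(seed, p = 48, k = 6) {
  set.seed(seed)
  memb <- rep(seq_len(k), each = p / k)
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (memb[i] == memb[j] && runif(1) < 0.6)
      W[i, j] <- W[j, i] <- runif(1, 0.1, 0.3)
    else if (memb[i] != memb[j] && runif(1) < 0.03)
      W[i, j] <- W[j, i] <- -runif(1, 0.05, 0.2)
  }
  list(net = signed_network(W, sprintf("n%02d", seq_len(p))), memb = memb)
}

test_that("spinglass splits two positive cliques joined by a negative edge", {
  net <- two_cliques()
  truth <- rep(1:2, each = 4)
  for (s in 1:10) {
    part <- spinglass_partition(net, seed = s, n_restarts = 5)
    expect_equal(adjusted_rand_index(part$assignment, truth), 1.0)
    expect_equal(part$K, 2L)
  }
})

test_that("an all-positive complete graph forms a single module", {
  W <- matrix(0.2, 6, 6); diag(W) <- 0
  part <- spinglass_partition(signed_network(W, sprintf("n%d", 1:6)),
                              seed = 3, n_restarts = 5)
  expect_equal(part$K, 1L)
})

test_that("returned partition beats trivial partitions in energy", {
  b <- planted_blocks(5)
  part <- spinglass_partition(b$net, seed = 5, n_restarts = 5)
  h_all_one <- spinglass_hamiltonian(b$net, rep(1L, 48))
  h_singletons <- spinglass_hamiltonian(b$net, seq_len(48))
  expect_lte(part$hamiltonian, h_all_one)
  expect_lte(part$hamiltonian, h_singletons)
})

test_that("module labels are canonical: module 1 is the largest", {
  b <- planted_blocks(7)
  part <- spinglass_partition(b$net, seed = 7, n_restarts = 5)
  sizes <- table(part$assignment)
  expect_equal(as.integer(names(sizes)), seq_len(part$K))
  expect_true(all(diff(as.integer(sizes)) <= 0))
})

test_that("signed modularity has its textbook values", {
  # single community covering an all-positive graph: Q = 0
  W <- matrix(0.4, 4, 4); diag(W) <- 0
  net <- signed_network(W, letters[1:4])
  expect_equal(signed_modularity(net, rep(1L, 4)), 0)
  # two disconnected positive cliques, correct split: Q = 0.5
  W2 <- matrix(0, 6, 6)
  W2[1:3, 1:3] <- 0.5; W2[4:6, 4:6] <- 0.5; diag(W2) <- 0
  net2 <- signed_network(W2, letters[1:6])
  expect_equal(signed_modularity(net2, rep(1:2, each = 3)), 0.5)
  # no negative edges: equals Newman weighted modularity via igraph
  b <- planted_blocks(11)
  Wp <- pmax(b$net$W, 0)
  netp <- signed_network(Wp, sprintf("n%02d", 1:48))
  g <- igraph::graph_from_adjacency_matrix(Wp, "undirected",
                                           weighted = TRUE)
  expect_equal(signed_modularity(netp, b$memb),
               igraph::modularity(g, b$memb, weights = igraph::E(g)$weight),
               tolerance = 1e-12)
  expect_error(signed_modularity(signed_network(matrix(0, 3, 3),
                                                letters[1:3]),
                                 rep(1, 3)), "no edges")
})

test_that("random assignments score near-zero modularity", {
  b <- planted_blocks(13)
  qs <- vapply(1:20, function(s) {
    set.seed(200 + s)
    signed_modularity(b$net, sample(1:6, 48, replace = TRUE))
  }, numeric(1))
  expect_true(all(abs(qs) < 0.1))
})

test_that("transitivity matches exhaustive triple counting", {
  # triangle
  W <- matrix(0.3, 3, 3); diag(W) <- 0
  expect_equal(transitivity(signed_network(W, letters[1:3])), 1.0)
  # 3-node path
  W2 <- matrix(0, 3, 3); W2[1, 2] <- W2[2, 1] <- W2[2, 3] <- W2[3, 2] <- 0.3
  expect_equal(transitivity(signed_network(W2, letters[1:3])), 0)
  # 4-cycle plus one diagonal: 2 triangles, 8 connected triples
  # (sum over centers of C(deg, 2) = 3 + 1 + 3 + 1) -> 6/8
  W3 <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3)))
    W3[e[1], e[2]] <- W3[e[2], e[1]] <- 0.2
  expect_equal(transitivity(signed_network(W3, letters[1:4])), 0.75)
  expect_equal(transitivity(signed_network(W3, letters[1:4])),
               oracle_transitivity(W3))
  # random graphs vs oracle
  for (s in 1:5) {
    W4 <- random_signed_network(sample(5:10, 1), seed = 300 + s)
    net <- signed_network(W4, sprintf("n%02d", seq_len(nrow(W4))))
    expect_equal(transitivity(net), oracle_transitivity(W4))
  }
  expect_warning(
    transitivity(signed_network(matrix(0, 3, 3), letters[1:3])),
    "no connected triples")
})

test_that("structural equivalence finds duplicated profiles", {
  set.seed(42)
  W <- random_signed_network(6, seed = 31)
  W <- rbind(cbind(W, W[, 6]), c(W[6, ], 0))  # node 7 duplicates node 6
  net <- signed_network(W, sprintf("n%d", 1:7))
  eq <- structural_equivalence(net, threshold = 0.95)
  expect_true(any(eq$a == "n6" & eq$b == "n7"))
  expect_equal(eq$correlation[eq$a == "n6" & eq$b == "n7"], 1.0)
  # random sparse networks rarely contain equivalent pairs at 0.95
  W2 <- random_signed_network(8, seed = 33, edge_prob = 0.3)
  eq2 <- structural_equivalence(signed_network(W2, sprintf("n%d", 1:8)),
                                threshold = 0.95)
  expect_lte(nrow(eq2), 1)
  # threshold -1 reports every comparable pair
  eq3 <- structural_equivalence(net, threshold = -1)
  expect_equal(nrow(eq3), choose(7, 2))
})

test_that("one-way ANOVA recovers group separation and drops singletons", {
  set.seed(55)
  # same mean and variance: no signal
  v0 <- rnorm(30)
  g0 <- rep(letters[1:3], each = 10)
  null_fit <- module_attribute_anova(v0, g0)
  expect_gt(null_fit$p, 0.05)
  # separated means: strong signal
  v1 <- c(rnorm(10, 0), rnorm(10, 3))
  g1 <- rep(c("x", "y"), each = 10)
  alt_fit <- module_attribute_anova(v1, g1)
  expect_lt(alt_fit$p, 0.001)
  expect_equal(unname(alt_fit$group_means["y"] - alt_fit$group_means["x"]),
               mean(v1[11:20]) - mean(v1[1:10]))
  # matches stats::aov directly
  ref <- anova(aov(v1 ~ factor(g1)))
  expect_equal(alt_fit$F, ref$`F value`[1])
  # singleton group dropped with warning; single remaining group errors
  expect_warning(module_attribute_anova(c(v1, 5), c(g1, "z")), "z")
  expect_error(
    suppressWarnings(module_attribute_anova(c(rnorm(5), 1),
                                            c(rep("a", 5), "b"))),
    "2 groups")
})

test_that("module composition cross-tabulates metadata attributes", {
  meta <- data.frame(node_id = letters[1:6],
                     module_id = rep(1:2, each = 3),
                     cell_type = c("neuronal", "neuronal", "mixed",
                                   "neuronal", "mixed", "mixed"))
  tabs <- module_composition(meta, attrs = "cell_type")
  expect_equal(unname(tabs$cell_type["1", "neuronal"]), 2L)
  expect_equal(unname(tabs$cell_type["2", "mixed"]), 2L)
})
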