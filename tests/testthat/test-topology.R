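tri_net <- function(w = c(0.2, 0.2, 0.2)) {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- w[1]
  W[1, 3] <- W[3, 1] <- w[2]
  W[2, 3] <- W[3, 2] <- w[3]
  signed_network(W, sprintf("n%d", 1:3))
}

test_that("strength sums absolute weights, expected influence keeps signs", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.4
  W[1, 3] <- W[3, 1] <- -0.1
  net <- signed_network(W, c("a", "b", "c"))
  expect_equal(unname(strength(net)["a"]), 0.5)
  expect_equal(unname(expected_influence(net)["a"]), 0.3)
  # triangle with equal weights: each node 0.4
  expect_equal(unname(strength(tri_net())), rep(0.4, 3))
  # all-negative edges give negative expected influence
  Wn <- -abs(W)
  netn <- signed_network(Wn, c("a", "b", "c"))
  expect_lt(expected_influence(netn)["a"], 0)
  # isolated node
  expect_equal(unname(strength(net)["b"]), 0.4)
})

test_that("EI equals strength exactly on all-positive networks", {
  for (s in 1:5) {
    W <- abs(random_signed_network(6, seed = s))
    net <- signed_network(W, sprintf("n%d", 1:6))
    expect_equal(expected_influence(net), strength(net))
  }
})

test_that("path lengths are reciprocal absolute weights", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- -0.5
  net <- signed_network(W, c("a", "b", "c"))
  D <- shortest_path_lengths(net)
  expect_equal(D["a", "c"], 4)        # 2 + 2
  expect_equal(D["a", "b"], 2)
  # disconnected pair is infinite
  W4 <- matrix(0, 4, 4); W4[1, 2] <- W4[2, 1] <- 0.25
  D4 <- shortest_path_lengths(signed_network(W4, sprintf("n%d", 1:4)))
  expect_equal(D4[1, 2], 4)
  expect_equal(D4[1, 3], Inf)
})

test_that("closeness and betweenness match hand-derived values", {
  # 3-node path with unit lengths (|w| = 1)
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  net <- signed_network(W, c("a", "b", "c"))
  expect_equal(unname(closeness(net)), c(1 / 3, 1 / 2, 1 / 3))
  expect_equal(unname(betweenness(net)), c(0, 1, 0))
  # complete graph, equal lengths: all c = 1/((p-1) l)
  p <- 4
  Wc <- matrix(0.5, p, p); diag(Wc) <- 0
  netc <- signed_network(Wc, sprintf("n%d", 1:p))
  expect_equal(unname(closeness(netc)), rep(1 / ((p - 1) * 2), p))
  # 4-cycle: two tied shortest paths per opposite pair -> 0.5 each
  W4 <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
    W4[e[1], e[2]] <- W4[e[2], e[1]] <- 0.5
  expect_equal(unname(betweenness(signed_network(W4, sprintf("n%d", 1:4)))),
               rep(0.5, 4))
  # star with 4 leaves: center lies on C(4,2) = 6 pairs
  W5 <- matrix(0, 5, 5)
  W5[1, 2:5] <- W5[2:5, 1] <- 0.3
  b5 <- betweenness(signed_network(W5, sprintf("n%d", 1:5)))
  expect_equal(unname(b5), c(6, 0, 0, 0, 0))
  # isolated node gets closeness 0
  W6 <- matrix(0, 3, 3); W6[1, 2] <- W6[2, 1] <- 0.5
  expect_equal(unname(closeness(signed_network(W6, c("a", "b", "c")))["c"]),
               0)
})

test_that("centralities agree with brute-force enumeration on random graphs", {
  for (s in 1:10) {
    p <- sample(4:8, 1)
    W <- random_signed_network(p, seed = 100 + s)
    net <- signed_network(W, sprintf("n%d", seq_len(p)))
    expect_equal(unname(betweenness(net)), oracle_betweenness(W),
                 tolerance = 1e-9)
    expect_equal(unname(closeness(net)), unname(oracle_closeness(W)),
                 tolerance = 1e-12)
    D <- shortest_path_lengths(net)
    expect_equal(unname(D), unname(oracle_distances(W)), tolerance = 1e-12)
  }
})

test_that("hub rule thresholds betweenness at mean plus two sd", {
  b <- setNames(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 30), sprintf("n%d", 1:10))
  # mean 3, sample sd ~ 9.49, threshold ~ 21.97
  expect_equal(identify_hubs(b), "n10")
  expect_equal(identify_hubs(setNames(c(0, 0, 0, 0, 10), letters[1:5])),
               character())  # 10 < 2 + 2 * 4.47
  expect_equal(identify_hubs(setNames(rep(2, 5), letters[1:5])),
               character())
  # invariant to relabeling
  b2 <- b[sample(names(b))]
  expect_setequal(identify_hubs(b2), identify_hubs(b))
  expect_error(identify_hubs(c(a = 1, b = 2)), "3 nodes")
})

test_that("connectivity sums decompose over layer pairs", {
  W <- matrix(0, 5, 5)
  W[1, 2] <- W[2, 1] <- 0.5
  W[3, 4] <- W[4, 3] <- -0.3
  W[1, 3] <- W[3, 1] <- 0.2
  layers <- c("synaptic_peptide", "synaptic_peptide",
              "pathological_peptide", "pathological_peptide",
              "cellular_pathology")
  net <- multilayer_network(signed_network(
    W, data.frame(node_id = sprintf("n%d", 1:5), layer = layers)))
  expect_equal(global_connectivity(net), 1.0)
  expect_equal(interlayer_connectivity(net, "synaptic_peptide",
                                       "pathological_peptide"), 0.2)
  expect_equal(interlayer_connectivity(net, "synaptic_peptide",
                                       "cellular_pathology"), 0)
  # partition identity: intra + inter sums recover the global value
  lys <- unique(layers)
  total <- sum(vapply(lys, function(l)
    interlayer_connectivity(net, l, l), numeric(1)))
  prs <- combn(lys, 2)
  total <- total + sum(vapply(seq_len(ncol(prs)), function(k)
    interlayer_connectivity(net, prs[1, k], prs[2, k]), numeric(1)))
  expect_equal(total, global_connectivity(net))
  # doubling weights doubles connectivity
  net2 <- multilayer_network(signed_network(
    2 * W, data.frame(node_id = sprintf("n%d", 1:5), layer = layers)))
  expect_equal(global_connectivity(net2), 2)
  expect_error(interlayer_connectivity(net, "synaptic_peptide", "nope"),
               "unknown layer")
})

test_that("diameter follows the configured length convention", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.5
  net <- signed_network(W, c("a", "b", "c"))
  expect_equal(diameter(net), 4)               # 2 + 2 on 1/|w|
  expect_equal(diameter(net, "hops"), 2)
  W1 <- matrix(0, 2, 2); W1[1, 2] <- W1[2, 1] <- 0.7
  expect_equal(diameter(signed_network(W1, c("a", "b")), "hops"), 1)
})

test_that("power-law fit distinguishes Pareto from Poisson-like tails", {
  set.seed(91)
  pareto <- 1 * runif(500)^(-1 / 1.5)   # alpha = 2.5
  fit <- powerlaw_ks_test(pareto, n_boot = 200, seed = 92)
  expect_gt(fit$p_value, 0.1)
  expect_lt(abs(fit$alpha - 2.5), 0.3)
  set.seed(93)
  pois <- rpois(500, 20) + 1
  fit2 <- powerlaw_ks_test(pois, n_boot = 200, seed = 94)
  expect_lt(fit2$p_value, 0.05)
  expect_error(powerlaw_ks_test(rep(2, 20)), "equal")
})

test_that("centrality table flags hubs and z-scores every measure", {
  W <- matrix(0, 12, 12)
  W[1, 2:12] <- W[2:12, 1] <- 0.4   # star: node 1 is the hub
  W[2, 3] <- W[3, 2] <- 0.2
  net <- multilayer_network(signed_network(
    W, data.frame(node_id = sprintf("n%02d", 1:12),
                  layer = rep("synaptic_peptide", 12))))
  tab <- centrality_table(net)
  expect_true(tab$hub_flag[1])
  expect_equal(sum(tab$hub_flag), 1)
  expect_equal(mean(tab$z_strength), 0, tolerance = 1e-12)
  expect_equal(sd(tab$z_betweenness), 1, tolerance = 1e-12)
})
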