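test_that("planted precision matrices are SPD with the designed pattern", {
  cfg <- synthetic_config(seed = 2)
  pr <- build_precision(cfg)
  expect_gt(min(eigen(pr$Theta, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  expect_equal(dim(pr$Theta), c(71L, 71L))
  expect_equal(as.numeric(table(factor(pr$node_meta$layer,
                                       levels = LAYERS))),
               c(48, 4, 14, 5))
  # sign pattern of W is the designed pattern (no eigenvalue bumping)
  off <- upper.tri(pr$Theta)
  expect_true(all(sign(pr$W[off]) == -sign(pr$Theta[off]) |
                    pr$Theta[off] == 0))
  # empty specification degenerates to independence
  cfg0 <- synthetic_config(seed = 2, module_sizes = integer(),
                           p_within = 0, n_negative_between = 0L,
                           hub_spec = list(), interlayer = list(),
                           layer_sizes = c(synaptic_peptide = 9L,
                                           ppi_complex = 0L,
                                           pathological_peptide = 0L,
                                           cellular_pathology = 0L))
  pr0 <- build_precision(cfg0)
  expect_equal(sum(abs(pr0$W)), 0)
})

test_that("hub rows carry the requested extra degree", {
  cfg <- synthetic_config(seed = 3)
  pr <- build_precision(cfg)
  deg <- rowSums(abs(pr$W) > 0)
  syn <- pr$node_meta$layer == "synaptic_peptide"
  expect_gt(deg[["STXBP1_6"]], median(deg[syn]))
  expect_gte(deg[["STXBP1_6"]], 5)
})

test_that("the group-unique edge is calibrated and group-specific", {
  cfg <- synthetic_config(seed = 4)
  ph <- build_precision(cfg, include_group_edges = FALSE)
  pl <- build_precision(cfg, include_group_edges = TRUE)
  expect_equal(ph$W["CPLX2_2", "tau_AT8_s202"], 0)
  expect_equal(pl$W["CPLX2_2", "tau_AT8_s202"], -0.4, tolerance = 1e-6)
  # the two matrices differ only at the planted entry
  d <- abs(ph$Theta - pl$Theta) > 0
  diag(d) <- FALSE
  d["CPLX2_2", "tau_AT8_s202"] <- d["tau_AT8_s202", "CPLX2_2"] <- FALSE
  d[cbind(c("CPLX2_2", "tau_AT8_s202"), c("CPLX2_2", "tau_AT8_s202"))] <- FALSE
  expect_equal(sum(d), 0)
})

test_that("sampling reproduces the planted covariance as n grows", {
  cfg <- synthetic_config(seed = 5)
  pr <- build_precision(cfg)
  Sigma <- chol2inv(chol(pr$Theta))
  err <- vapply(c(500, 2000), function(n) {
    g <- sample_group(pr$Theta, n, "identity", 0, seed = n)
    norm(cov(g$X) - Sigma, "F")
  }, numeric(1))
  expect_lt(err[2], err[1] * 0.75)
})

test_that("MCAR masking hits the requested rate", {
  cfg <- synthetic_config(seed = 6)
  pr <- build_precision(cfg)
  g <- sample_group(pr$Theta, 400, "identity", 0.1, seed = 7)
  rate <- mean(is.na(g$X))
  expect_lt(abs(rate - 0.1), 0.01)
})

test_that("monotone marginal transforms vanish under the npn transform", {
  cfg <- synthetic_config(seed = 8)
  pr <- build_precision(cfg)
  g <- sample_group(pr$Theta[1:5, 1:5], 200,
                    c("identity", "exp", "cube", "identity", "exp"),
                    0, seed = 9)
  expect_equal(nonparanormal_transform(g$X),
               nonparanormal_transform(g$latent), ignore_attr = TRUE)
})

test_that("generated studies are seed-reproducible and seed-sensitive", {
  s1 <- generate_study(synthetic_config(n_per_group = 30, seed = 10))
  s2 <- generate_study(synthetic_config(n_per_group = 30, seed = 10))
  s3 <- generate_study(synthetic_config(n_per_group = 30, seed = 11))
  expect_identical(s1$high$X, s2$high$X)
  expect_identical(s1$low$covariates, s2$low$covariates)
  expect_false(identical(s1$high$X, s3$high$X))
})

test_that("study phenotypes and grouping obey the design", {
  st <- generate_study(synthetic_config(seed = 12))
  # median split of pooled activity reproduces the group labels
  act <- c(st$high$covariates$activity, st$low$covariates$activity)
  names(act) <- c(st$high$covariates$subject_id,
                  st$low$covariates$subject_id)
  sp <- median_split(act)
  expect_true(all(grepl("^high", sp$high)))
  expect_true(all(grepl("^low", sp$low)))
  # group-unique edge present only in the low-group truth
  expect_equal(st$truth$W_high["CPLX2_2", "tau_AT8_s202"], 0)
  expect_lt(st$truth$W_low["CPLX2_2", "tau_AT8_s202"], -0.35)
  # cognition depends on module 2 the most strongly
  lat <- rbind(st$high$latent, st$low$latent)
  mods <- st$truth$modules
  m2 <- rowMeans(lat[, names(mods)[!is.na(mods) & mods == 2]])
  cog <- c(st$high$covariates$cognition_z, st$low$covariates$cognition_z)
  expect_gt(cor(m2, cog), 0.3)
})

test_that("written studies round-trip through the readers", {
  st <- generate_study(synthetic_config(n_per_group = 25, seed = 13))
  dir <- tempfile("study_")
  paths <- write_study(st, dir)
  meta <- read_node_meta(paths[["meta"]])
  expect_equal(meta$node_id, st$node_meta$node_id)
  tb <- read_subject_table(paths[["high"]])
  expect_equal(unname(tb$X[, meta$node_id]), unname(st$high$X),
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("full-pipeline recovery from default study conditions", {
  # edge recovery (per group, n = 220) and synaptic module recovery;
  # deeper multi-seed versions of these checks run in the acceptance suite
  st <- generate_study(synthetic_config(seed = 14))
  Wl <- synaptnet:::.estimate_W(st$low$X, n_lambda = 40)
  expect_gte(edge_f1(Wl, st$truth$W_low), 0.7)
  syn <- st$node_meta$node_id[st$node_meta$layer == "synaptic_peptide"]
  Ws <- synaptnet:::.estimate_W(rbind(st$high$X, st$low$X)[, syn],
                                n_lambda = 40)
  net <- signed_network(Ws, st$node_meta[match(syn,
                                               st$node_meta$node_id), ])
  part <- spinglass_partition(net, seed = 14, n_restarts = 10)
  expect_gte(adjusted_rand_index(part$assignment[syn],
                                 st$truth$modules[syn]), 0.7)
})
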