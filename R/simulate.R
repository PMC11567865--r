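# Synthetic multilayer data with known ground truth: sparse signed
# precision structure (modules, hubs, inter-layer edges, one
# group-specific negative edge), Gaussian-copula sampling with non-normal
# monotone marginals and MCAR missingness, and phenotypes carrying
# planted regression effects. Stands in for the access-controlled cohort
# data so that every pipeline stage is testable against truth.

.default_node_meta <- function(layer_sizes, module_sizes) {
  syn_named <- c("STX1A", "SNAP25_1", "SYT12_1", "STXBP1_4", "STXBP1_6",
                 "VAMP1", "CPLX2_1", "CPLX2_2")
  n_syn <- layer_sizes[["synaptic_peptide"]]
  syn <- c(syn_named, sprintf("SYN_%02d", seq_len(n_syn - length(syn_named))))
  ppi <- c("STX_SNAP25", "SNAP25_VAMP", "STX_VAMP", "SNARE_total")[
    seq_len(layer_sizes[["ppi_complex"]])]
  path_named <- c("tau_AT8_s202", "tau_AT100_t217", "tau_12E8_s262",
                  "abeta_40", "abeta_42", "app_1")
  n_path <- layer_sizes[["pathological_peptide"]]
  path <- c(path_named[seq_len(min(length(path_named), n_path))],
            sprintf("tau_%02d", seq_len(max(0, n_path - length(path_named)))))
  cell <- c("tangles_AT8", "tangles_silver", "amyloid_IHC",
            "diffuse_plaques", "neuritic_plaques")[
    seq_len(layer_sizes[["cellular_pathology"]])]
  ids <- c(syn, ppi, path, cell)
  layer <- rep(LAYERS, times = c(length(syn), length(ppi), length(path),
                                 length(cell)))
  meta <- data.frame(node_id = ids, label = ids, layer = layer,
                     function_tag = NA_character_,
                     cell_type = NA_character_,
                     localization = NA_character_,
                     stringsAsFactors = FALSE)
  # planted module structure on the synaptic layer; module 2 holds the
  # secretion peptides localized to membranes, module 1 cytosolic secretion
  meta$true_module <- NA_integer_
  syn_idx <- which(meta$layer == "synaptic_peptide")
  mod <- rep(seq_along(module_sizes), times = module_sizes)[
    seq_along(syn_idx)]
  # pin the named secretion peptides to modules 1/2 by label swaps
  pin <- function(mod, pos, m) {
    if (mod[pos] != m) {
      donor <- which(mod == m & !(seq_along(mod) %in% pos))[1]
      mod[donor] <- mod[pos]
      mod[pos] <- m
    }
    mod
  }
  if (length(module_sizes) >= 2) {
    for (id in c("STX1A", "SNAP25_1", "SYT12_1"))
      mod <- pin(mod, match(id, meta$node_id[syn_idx]), 2L)
    for (id in c("STXBP1_6", "STXBP1_4", "VAMP1"))
      mod <- pin(mod, match(id, meta$node_id[syn_idx]), 1L)
  }
  meta$true_module[syn_idx] <- mod
  tm <- mod
  meta$function_tag[syn_idx] <- ifelse(tm %in% c(1, 2), "secretion",
                                       ifelse(tm %in% c(3, 4), "trafficking",
                                              "other"))
  meta$cell_type[syn_idx] <- ifelse(tm %in% c(1, 2), "neuronal", "mixed")
  meta$localization[syn_idx] <- ifelse(tm == 2, "plasma_membrane",
                                       ifelse(tm == 1, "cytosol", "other"))
  meta
}

#' Default synthetic study configuration
#'
#' The defaults emulate the study conditions of the cohort the pipeline
#' targets: 220 subjects per activity group, a 71-node 4-layer network
#' (48 synaptic peptides / 4 protein-protein interaction measures /
#' 14 pathological peptides / 5 cellular pathology densities), six
#' synaptic modules of 2-14 nodes, a betweenness hub in each of the
#' synaptic and pathological layers, one negative synaptic-to-p-tau edge
#' present only in the low-activity group (partial correlation -0.4), a
#' planted unbalanced (+,+,-) triad among the two p-tau hubs and the
#' tangle node, non-normal monotone marginals, 5% MCAR missingness,
#' lognormal activity counts (mean 1.94, SD 1.14), cognition weighted on
#' modules 1 and 2 (0.55 / 1.68), and a three-way
#' p-tau x module-2 x activity coefficient of 0.65 on tangle burden.
#'
#' @param n_per_group subjects per activity group.
#' @param seed master seed; all randomness derives from it.
#' @param ... overrides for any configuration entry.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_group = 220, seed = 1, ...) {
  cfg <- list(
    n_per_group = n_per_group,
    layer_sizes = c(synaptic_peptide = 48L, ppi_complex = 4L,
                    pathological_peptide = 14L, cellular_pathology = 5L),
    module_sizes = c(10L, 12L, 8L, 7L, 5L, 6L),
    p_within = 0.12,
    weight_range = c(2, 3.2),
    n_negative_between = 10L,
    negative_weight_range = c(1.2, 1.8),
    hub_spec = list(list(node = "STXBP1_6", degree = 5L, weight = 4),
                    list(node = "tau_AT8_s202", degree = 6L, weight = 4.5)),
    interlayer = list(
      list(layers = c("synaptic_peptide", "pathological_peptide"),
           count = 6L, sign = -1, range = c(1.2, 1.8)),
      list(layers = c("synaptic_peptide", "ppi_complex"),
           count = 6L, sign = 1, range = c(1.2, 1.8)),
      list(layers = c("pathological_peptide", "cellular_pathology"),
           count = 4L, sign = 1, range = c(1.2, 1.8))),
    group_unique_edges = list(list(a = "CPLX2_2", b = "tau_AT8_s202",
                                   pcor = -0.4, group = "low")),
    marginal_transforms = c("identity", "exp", "cube"),
    missing_rate = 0.05,
    phenotype_spec = list(
      cognition_weights = c(0.55, 1.68, 0, 0, 0, 0),
      cognition_sd = 1,
      age_effect = -0.02, education_effect = 0.03,
      tangle_betas = c(ptau_1 = 1.08, ptau_2 = -0.97, module = -1.11),
      beta3 = 0.65, tangle_sd = 0.36,
      ptau_1 = "tau_AT100_t217", ptau_2 = "tau_AT8_s202",
      cognition_modules = c(1, 2)),
    activity = list(meanlog = 0.515, sdlog = 0.545),
    demographics = list(age_mean = 90.6, age_sd = 6.2, male_frac = 0.266,
                        edu_mean = 14.6, edu_sd = 2.8),
    seed = seed)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "synthetic_config")
}

#' Assemble the planted precision matrix
#'
#' Builds a sparse signed symmetric precision matrix from module blocks
#' (positive within-module edges), negative between-module edges, hub
#' rows, inter-layer edges and an unbalanced p-tau/tangle triad. The
#' diagonal is set to 1 + the row's absolute off-diagonal sum, which
#' makes the matrix strictly diagonally dominant (hence SPD) while
#' preserving the designed sign pattern exactly. Group-unique edges are
#' calibrated so the implied partial correlation matches the requested
#' value.
#'
#' @param config a [synthetic_config()].
#' @param include_group_edges add the group-unique edges ("low"-group
#'   variant).
#' @return list with `Theta` (precision), `W` (implied true partial
#'   correlations), `node_meta` (with `true_module`), `hubs`.
#' @export
build_precision <- function(config, include_group_edges = FALSE) {
  ls <- config$layer_sizes
  meta <- .default_node_meta(ls, config$module_sizes)
  p <- nrow(meta)
  ids <- meta$node_id
  Theta <- matrix(0, p, p, dimnames = list(ids, ids))
  wr <- config$weight_range
  with_seed(config$seed, {
    syn <- which(meta$layer == "synaptic_peptide")
    # module blocks: positive conditional dependencies within module
    for (m in seq_along(config$module_sizes)) {
      memb <- syn[meta$true_module[syn] == m]
      if (length(memb) < 2) next
      prs <- t(combn(memb, 2))
      pick <- runif(nrow(prs)) < config$p_within
      # guarantee connectivity of the block with a spanning chain
      for (i in seq_len(length(memb) - 1)) {
        Theta[memb[i], memb[i + 1]] <- -runif(1, wr[1], wr[2])
      }
      for (k in which(pick)) {
        Theta[prs[k, 1], prs[k, 2]] <- -runif(1, wr[1], wr[2])
      }
    }
    # sparse negative edges between modules
    nwr <- config$negative_weight_range
    placed <- 0
    while (placed < config$n_negative_between) {
      ij <- sample(syn, 2)
      if (meta$true_module[ij[1]] == meta$true_module[ij[2]]) next
      if (Theta[ij[1], ij[2]] != 0 || Theta[ij[2], ij[1]] != 0) next
      Theta[min(ij), max(ij)] <- runif(1, nwr[1], nwr[2])
      placed <- placed + 1
    }
    # hubs: spokes from the named node into distinct modules (synaptic
    # layer) or spread along the layer (others), creating a gatekeeper
    for (h in config$hub_spec) {
      i <- match(h$node, ids)
      if (meta$layer[i] == "synaptic_peptide") {
        own <- meta$true_module[i]
        mods <- setdiff(unique(meta$true_module[syn]), own)
        tgt <- vapply(mods, function(m)
          sample(setdiff(syn[meta$true_module[syn] == m], i), 1), integer(1))
        tgt <- tgt[seq_len(min(h$degree, length(tgt)))]
      } else {
        pool <- setdiff(which(meta$layer == meta$layer[i]), i)
        tgt <- sample(pool, min(h$degree, length(pool)))
      }
      for (j in tgt) {
        a <- min(i, j); b <- max(i, j)
        if (Theta[a, b] == 0) Theta[a, b] <- -h$weight * runif(1, 0.8, 1.2)
      }
    }
    # within-layer structure for the small layers (positive chains)
    for (ly in c("ppi_complex", "pathological_peptide",
                 "cellular_pathology")) {
      memb <- which(meta$layer == ly)
      for (i in seq_len(max(length(memb) - 1, 0)))
        Theta[memb[i], memb[i + 1]] <- -runif(1, wr[1], wr[2])
    }
    # inter-layer edges
    for (il in config$interlayer) {
      a_pool <- which(meta$layer == il$layers[1])
      b_pool <- which(meta$layer == il$layers[2])
      placed <- 0
      while (placed < il$count) {
        i <- sample(a_pool, 1); j <- sample(b_pool, 1)
        a <- min(i, j); b <- max(i, j)
        if (Theta[a, b] != 0) next
        Theta[a, b] <- -il$sign * runif(1, il$range[1], il$range[2])
        placed <- placed + 1
      }
    }
  })
  Theta[lower.tri(Theta)] <- 0
  Theta <- Theta + t(Theta)
  # entries with target partial correlations, calibrated jointly below:
  # the unbalanced (+,+,-) triad among the p-tau nodes and the tangle
  # node, plus (low group only) the group-unique edge
  shared <- list(
    list(a = "tau_AT100_t217", b = "tau_AT8_s202", pcor = 0.35),
    list(a = "tau_AT100_t217", b = "tangles_AT8", pcor = 0.3),
    list(a = "tau_AT8_s202", b = "tangles_AT8", pcor = -0.3))
  # fixed point: theta_ij = -pcor * sqrt(d_i d_j) with the diagonal
  # d = 1 + row absolute sum depending on the calibrated entries; the
  # shared (both-group) targets are calibrated first so the two group
  # matrices differ off-diagonal only at the group-unique entries
  calibrate <- function(Theta, targets) {
    targets <- Filter(function(t) !anyNA(match(c(t$a, t$b), ids)), targets)
    for (it in 1:50) {
      d <- 1 + rowSums(abs(Theta)) - diag(abs(Theta))
      for (tg in targets) {
        i <- match(tg$a, ids); j <- match(tg$b, ids)
        Theta[i, j] <- Theta[j, i] <- -tg$pcor * sqrt(d[i] * d[j])
      }
    }
    Theta
  }
  Theta <- calibrate(Theta, shared)
  if (include_group_edges)
    Theta <- calibrate(Theta, config$group_unique_edges)
  diag(Theta) <- 0
  diag(Theta) <- 1 + rowSums(abs(Theta))
  ev <- min(eigen(Theta, symmetric = TRUE, only.values = TRUE)$values)
  stopifnot(ev > 0)
  W <- to_partial_correlations(Theta)
  hubs <- vapply(config$hub_spec, function(h) h$node, character(1))
  list(Theta = Theta, W = W, node_meta = meta, hubs = hubs)
}

.apply_transforms <- function(Z, transforms) {
  p <- ncol(Z)
  tr <- rep(transforms, length.out = p)
  X <- Z
  for (j in seq_len(p)) {
    X[, j] <- switch(tr[j], identity = Z[, j], exp = exp(Z[, j]),
                     cube = Z[, j]^3,
                     stop("unknown marginal transform: ", tr[j]))
  }
  X
}

#' Sample one group from a planted precision matrix
#'
#' Draws n multivariate normal rows with covariance `solve(Theta)`,
#' applies per-column strictly monotone marginal transforms
#' (Gaussian-copula construction consistent with the nonparanormal
#' model), then masks entries missing completely at random.
#'
#' @param Theta SPD precision matrix.
#' @param n number of subjects.
#' @param marginal_transforms recycled vector of "identity", "exp",
#'   "cube".
#' @param missing_rate MCAR masking fraction.
#' @param seed RNG seed.
#' @return list with `X` (observed, transformed, with NA) and `latent`
#'   (the complete Gaussian draws).
#' @export
sample_group <- function(Theta, n, marginal_transforms = "identity",
                         missing_rate = 0, seed = 1) {
  p <- nrow(Theta)
  Sigma <- chol2inv(chol(Theta))
  L <- chol(Sigma)
  with_seed(seed, {
    Z <- matrix(rnorm(n * p), n, p) %*% L
    colnames(Z) <- colnames(Theta)
    X <- .apply_transforms(Z, marginal_transforms)
    if (missing_rate > 0)
      X[matrix(runif(n * p) < missing_rate, n, p)] <- NA
    list(X = X, latent = Z)
  })
}

#' Generate a full two-group synthetic study
#'
#' Two groups of `n_per_group` subjects share the planted precision
#' structure except for the group-unique edges (present only in the
#' low-activity group). Activity counts are drawn lognormal and split at
#' the pooled median so the median split reproduces the group labels;
#' cognition is a weighted sum of module mean levels plus demographic
#' effects and noise; tangle burden follows the moderation model with
#' the planted three-way coefficient.
#'
#' @param config a [synthetic_config()].
#' @return list with `high`, `low` (each: `X`, `latent`, `covariates`),
#'   `node_meta`, and `truth` (per-group Theta/W, module assignment,
#'   hubs, planted effects, seed).
#' @export
generate_study <- function(config = synthetic_config()) {
  ph <- build_precision(config, include_group_edges = FALSE)
  pl <- build_precision(config, include_group_edges = TRUE)
  n <- config$n_per_group
  gh <- sample_group(ph$Theta, n, config$marginal_transforms,
                     config$missing_rate, seed = config$seed + 101L)
  gl <- sample_group(pl$Theta, n, config$marginal_transforms,
                     config$missing_rate, seed = config$seed + 202L)
  meta <- ph$node_meta
  ps <- config$phenotype_spec
  act_cfg <- config$activity
  dm <- config$demographics
  with_seed(config$seed + 303L, {
    act <- rlnorm(2 * n, act_cfg$meanlog, act_cfg$sdlog)
    med <- median(act)
    act_high <- act[act > med][seq_len(n)]
    act_low <- act[act <= med][seq_len(n)]
    covs <- function(latent, activity, group) {
      nn <- nrow(latent)
      age <- rnorm(nn, dm$age_mean, dm$age_sd)
      sex <- rbinom(nn, 1, dm$male_frac)
      edu <- round(rnorm(nn, dm$edu_mean, dm$edu_sd))
      msc <- vapply(seq_along(config$module_sizes), function(m) {
        memb <- meta$node_id[!is.na(meta$true_module) &
                               meta$true_module == m]
        rowMeans(latent[, memb, drop = FALSE])
      }, numeric(nn))
      cog <- msc %*% ps$cognition_weights +
        ps$age_effect * (age - dm$age_mean) +
        ps$education_effect * (edu - dm$edu_mean) +
        rnorm(nn, 0, ps$cognition_sd)
      p1 <- latent[, ps$ptau_1]; p2 <- latent[, ps$ptau_2]
      m2 <- msc[, 2]
      act_c <- activity - exp(act_cfg$meanlog + act_cfg$sdlog^2 / 2)
      tangles <- ps$tangle_betas["ptau_1"] * p1 +
        ps$tangle_betas["ptau_2"] * p2 +
        ps$tangle_betas["module"] * m2 +
        ps$beta3 * p1 * m2 * act_c +
        rnorm(nn, 0, ps$tangle_sd)
      data.frame(subject_id = sprintf("%s_%03d", group, seq_len(nn)),
                 age = age, sex = sex, education = edu,
                 activity = activity, cognition_z = as.numeric(cog),
                 tangle_density = as.numeric(tangles),
                 stringsAsFactors = FALSE)
    }
    gh$covariates <- covs(gh$latent, act_high, "high")
    gl$covariates <- covs(gl$latent, act_low, "low")
  })
  truth <- list(Theta_high = ph$Theta, Theta_low = pl$Theta,
                W_high = ph$W, W_low = pl$W,
                modules = setNames(meta$true_module, meta$node_id),
                hubs = ph$hubs,
                group_unique_edges = config$group_unique_edges,
                phenotype_spec = ps, seed = config$seed)
  list(high = gh, low = gl, node_meta = meta, truth = truth)
}

#' Random sparse SPD precision matrix
#'
#' Utility for recovery experiments: a random sparse signed precision
#' with `prob` edge density, off-diagonal magnitudes in `weight_range`,
#' diagonal set to 1 + row absolute sum (diagonally dominant, SPD).
#'
#' @param p dimension.
#' @param prob edge probability.
#' @param weight_range magnitude range of precision off-diagonals.
#' @param neg_frac fraction of negative partial correlations.
#' @param seed RNG seed.
#' @return list with `Theta` and implied `W`.
#' @export
random_sparse_precision <- function(p, prob = 0.15,
                                    weight_range = c(0.4, 0.7),
                                    neg_frac = 0.3, seed = 1) {
  with_seed(seed, {
    Theta <- matrix(0, p, p)
    ut <- which(upper.tri(Theta))
    pick <- ut[runif(length(ut)) < prob]
    Theta[pick] <- -runif(length(pick), weight_range[1], weight_range[2]) *
      ifelse(runif(length(pick)) < neg_frac, -1, 1)
    Theta <- Theta + t(Theta)
    diag(Theta) <- 1 + rowSums(abs(Theta))
    colnames(Theta) <- rownames(Theta) <- sprintf("V%02d", seq_len(p))
    list(Theta = Theta, W = to_partial_correlations(Theta))
  })
}

#' Write a synthetic study to disk
#'
#' Emits the subject-by-variable CSVs the preprocessing stage reads, the
#' node metadata TSV, and a truth-bundle JSON.
#'
#' @param study output of [generate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- c(high = file.path(dir, "subjects_high.csv"),
           low = file.path(dir, "subjects_low.csv"),
           meta = file.path(dir, "node_meta.tsv"),
           truth = file.path(dir, "truth.json"))
  for (g in c("high", "low")) {
    d <- cbind(data.frame(subject_id = study[[g]]$covariates$subject_id),
               as.data.frame(study[[g]]$X),
               study[[g]]$covariates[, -1])
    write.csv(d, pth[[g]], row.names = FALSE, na = "")
  }
  write.table(study$node_meta, pth[["meta"]], sep = "\t", row.names = FALSE,
              quote = FALSE)
  tr <- study$truth
  tr$Theta_high <- NULL; tr$Theta_low <- NULL
  tr$W_high <- NULL; tr$W_low <- NULL
  jsonlite::write_json(tr, pth[["truth"]], auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(pth)
}
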