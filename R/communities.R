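# Signed spinglass module detection and module-level summaries.

#' Signed spinglass Hamiltonian
#'
#' Reichardt-Bornholdt energy with configuration-model null, negative-edge
#' extension: within-module positive weight is rewarded, within-module
#' negative weight penalized,
#' `H = -sum_(i<j) [w+_ij - gp p+_ij] d(s_i,s_j)
#'     + sum_(i<j) [w-_ij - gn p-_ij] d(s_i,s_j)`
#' with `p±_ij = s±_i s±_j / (2 m±)` from the positive/negative strength
#' sequences.
#'
#' @param net a `signed_network`.
#' @param assignment integer module label per node.
#' @param gamma_pos,gamma_neg resolution parameters (default 1).
#' @return numeric energy (lower is better).
#' @export
spinglass_hamiltonian <- function(net, assignment, gamma_pos = 1,
                                  gamma_neg = 1) {
  W <- net$W
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  same <- outer(assignment, assignment, "==")
  ut <- upper.tri(W)
  hp <- 0; hn <- 0
  mp2 <- sum(Wp)             # 2 m+
  if (mp2 > 0) {
    Pp <- tcrossprod(rowSums(Wp)) / mp2
    hp <- -sum(((Wp - gamma_pos * Pp) * same)[ut])
  }
  mn2 <- sum(Wn)
  if (mn2 > 0) {
    Pn <- tcrossprod(rowSums(Wn)) / mn2
    hn <- sum(((Wn - gamma_neg * Pn) * same)[ut])
  }
  hp + hn
}

#' Spinglass community detection on a signed network
#'
#' Simulated-annealing minimization of the signed spinglass Hamiltonian
#' (negative-edge extension of the Reichardt-Bornholdt Potts model),
#' run `n_restarts` times with the best-energy partition kept. Labels are
#' canonicalized by descending module size (ties by smallest member
#' index). Deterministic given `seed`. Disconnected networks are handled
#' by clustering the largest component and giving each remaining
#' component its own module.
#'
#' @param net a `signed_network` with at least one edge.
#' @param n_spins maximum number of modules (default 25).
#' @param gamma_pos,gamma_neg resolution parameters (default 1).
#' @param seed RNG seed.
#' @param n_restarts annealing restarts (default 20).
#' @param start_temp,stop_temp,cool_fact annealing schedule.
#' @return object of class `partition_result`: `assignment` (named integer
#'   vector), `K`, `modularity` (signed), `modularity_positive`,
#'   `transitivity`, `hamiltonian`, `seed`, `n_restarts`.
#' @export
spinglass_partition <- function(net, n_spins = 25, gamma_pos = 1,
                                gamma_neg = 1, seed = 1, n_restarts = 20,
                                start_temp = 1, stop_temp = 0.01,
                                cool_fact = 0.99) {
  if (nrow(net$W) < 3) stop("need at least 3 nodes")
  if (all(net$W == 0)) stop("network has no edges")
  g <- as_igraph(net)
  comp <- igraph::components(g)
  ids <- net$nodes$node_id
  assignment <- rep(NA_integer_, length(ids))
  names(assignment) <- ids
  main <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(g, main)
  has_neg <- any(igraph::E(sub)$weight < 0)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      cl <- igraph::cluster_spinglass(
        sub, spins = min(n_spins, igraph::vcount(sub)),
        implementation = if (has_neg) "neg" else "orig",
        gamma = gamma_pos, gamma.minus = gamma_neg,
        start.temp = start_temp, stop.temp = stop_temp,
        cool.fact = cool_fact)
      memb <- igraph::membership(cl)
      full <- assignment
      full[names(memb)] <- as.integer(memb)
      # other components: one module each
      extra <- max(memb)
      for (cc in setdiff(seq_len(comp$no), which.max(comp$csize))) {
        extra <- extra + 1L
        full[ids[comp$membership == cc]] <- extra
      }
      h <- spinglass_hamiltonian(net, full[ids], gamma_pos, gamma_neg)
      if (is.null(best) || h < best$h) best <- list(h = h, assignment = full)
    }
  })
  assignment <- canonicalize_labels(best$assignment[ids])
  structure(list(assignment = assignment, K = max(assignment),
                 modularity = signed_modularity(net, assignment),
                 modularity_positive = .newman_modularity(pmax(net$W, 0),
                                                          assignment),
                 transitivity = transitivity(net),
                 hamiltonian = best$h, seed = seed,
                 n_restarts = n_restarts),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf(
    "partition_result: K = %d modules, Q(signed) = %.3f, T = %.3f, H = %.3f\n",
    x$K, x$modularity, x$transitivity, x$hamiltonian))
  invisible(x)
}

canonicalize_labels <- function(assignment) {
  sizes <- table(assignment)
  firsts <- vapply(names(sizes), function(l) min(which(assignment == l)),
                   numeric(1))
  ord <- order(-as.numeric(sizes), firsts)
  relab <- setNames(seq_along(ord), names(sizes)[ord])
  out <- relab[as.character(assignment)]
  names(out) <- names(assignment)
  out
}

.newman_modularity <- function(A, assignment) {
  m2 <- sum(A)
  if (m2 <= 0) return(0)
  k <- rowSums(A)
  same <- outer(assignment, assignment, "==")
  sum(((A - tcrossprod(k) / m2) * same)) / m2
}

#' Signed modularity (Gomez decomposition)
#'
#' `Q = (2m+ Q+ - 2m- Q-) / (2m+ + 2m-)` where `Q±` are Newman weighted
#' modularities of the positive/negative weight parts and `m±` their total
#' weights. With no negative edges this is standard Newman weighted
#' modularity.
#'
#' @param net a `signed_network`.
#' @param assignment module label per node (in node order or named).
#' @return modularity Q in \[-1, 1\].
#' @export
signed_modularity <- function(net, assignment) {
  if (all(net$W == 0)) stop("network has no edges")
  if (!is.null(names(assignment)))
    assignment <- assignment[net$nodes$node_id]
  Wp <- pmax(net$W, 0); Wn <- pmax(-net$W, 0)
  mp2 <- sum(Wp); mn2 <- sum(Wn)
  qp <- if (mp2 > 0) .newman_modularity(Wp, assignment) else 0
  qn <- if (mn2 > 0) .newman_modularity(Wn, assignment) else 0
  (mp2 * qp - mn2 * qn) / (mp2 + mn2)
}

#' Transitivity (global clustering coefficient)
#'
#' `3 x closed triangles / connected triples` on the unweighted support of
#' the weight matrix.
#' @param net a `signed_network`.
#' @return T in \[0, 1\]; 0 (with a warning) when there are no triples.
#' @export
transitivity <- function(net) {
  A <- (abs(net$W) > 0) * 1
  tri <- sum(diag(A %*% A %*% A)) / 6
  deg <- rowSums(A)
  triples <- sum(deg * (deg - 1) / 2)
  if (triples == 0) {
    warning("no connected triples; transitivity undefined, returning 0")
    return(0)
  }
  3 * tri / triples
}

#' Structurally equivalent node pairs
#'
#' For each node pair, the Pearson correlation of their edge-weight
#' profiles to all third nodes (entries involving the pair itself
#' excluded); pairs at or above `threshold` are reported.
#'
#' @param net a `signed_network` with >= 3 nodes.
#' @param threshold correlation cutoff (default 0.95).
#' @return data frame `a`, `b`, `correlation` (possibly empty).
#' @export
structural_equivalence <- function(net, threshold = 0.95) {
  W <- net$W
  p <- nrow(W)
  if (p < 3) stop("need at least 3 nodes")
  ids <- net$nodes$node_id
  res <- list()
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    keep <- setdiff(seq_len(p), c(i, j))
    a <- W[i, keep]; b <- W[j, keep]
    if (sd(a) == 0 || sd(b) == 0) next
    r <- cor(a, b)
    if (!is.na(r) && r >= threshold)
      res[[length(res) + 1]] <- data.frame(a = ids[i], b = ids[j],
                                           correlation = r)
  }
  if (!length(res))
    return(data.frame(a = character(), b = character(),
                      correlation = numeric()))
  do.call(rbind, res)
}

#' One-way ANOVA of a node statistic across groups
#'
#' Fixed-effects one-way ANOVA of per-node values (e.g. expected
#' influence) across node groupings (modules, function tags). Groups with
#' fewer than 2 members are dropped with a warning.
#'
#' @param values numeric per-node statistic.
#' @param groups per-node group label.
#' @return list with `F`, `p`, `group_means`, `df`.
#' @export
module_attribute_anova <- function(values, groups) {
  groups <- as.character(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("dropping group(s) with < 2 members: ",
            paste(small, collapse = ", "))
    sel <- !groups %in% small
    values <- values[sel]; groups <- groups[sel]
  }
  if (length(unique(groups)) < 2)
    stop("need at least 2 groups with >= 2 members")
  fit <- aov(values ~ factor(groups))
  tab <- anova(fit)
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       group_means = tapply(values, groups, mean),
       df = tab$Df[1:2])
}

#' Module composition cross-tabulation
#'
#' Module-by-attribute counts for reporting (cell type, localization,
#' primary function).
#' @param node_meta node metadata with a `module_id` column.
#' @param attrs attribute columns to tabulate.
#' @return named list of contingency tables.
#' @export
module_composition <- function(node_meta,
                               attrs = c("cell_type", "localization",
                                         "function_tag")) {
  attrs <- intersect(attrs, names(node_meta))
  lapply(setNames(attrs, attrs), function(a)
    table(module = node_meta$module_id, node_meta[[a]]))
}
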