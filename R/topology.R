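# Node- and network-level analytics. Path-based measures use the
# inverse-absolute-weight length convention (stronger edge = shorter path),
# the convention of the weighted-network toolkits this field uses.

#' Node strength
#'
#' Sum of absolute edge weights per node: `s_i = sum_j |W_ij|`. Set
#' `absolute = FALSE` for the signed variant (then identical to
#' [expected_influence()]).
#' @param net a `signed_network`.
#' @param absolute sum |w| (default) or signed w.
#' @return named numeric vector.
#' @export
strength <- function(net, absolute = TRUE) {
  W <- if (absolute) abs(net$W) else net$W
  setNames(rowSums(W), net$nodes$node_id)
}

#' Expected influence
#'
#' One-step signed centrality: `EI_i = sum_j W_ij`, the sum of a node's
#' edges keeping both positive and negative signs.
#' @param net a `signed_network`.
#' @return named numeric vector.
#' @export
expected_influence <- function(net) strength(net, absolute = FALSE)

#' All-pairs shortest path lengths
#'
#' Edge length is `1 / |W_ij|`; Dijkstra all pairs; unreachable pairs
#' are `Inf`.
#' @param net a `signed_network`.
#' @return p x p matrix of distances (0 on the diagonal).
#' @export
shortest_path_lengths <- function(net) {
  g <- as_igraph(net, absolute = TRUE)
  if (igraph::ecount(g) == 0) {
    p <- nrow(net$W)
    D <- matrix(Inf, p, p, dimnames = list(net$nodes$node_id, net$nodes$node_id))
    diag(D) <- 0
    return(D)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight, algorithm = "dijkstra")
}

#' Closeness centrality
#'
#' Default is the reciprocal total distance within a node's connected
#' component: `c_i = 1 / sum_(j reachable) d(i, j)` with `d` the
#' inverse-absolute-weight shortest path; isolated nodes get 0.
#' `harmonic = TRUE` gives the sum of reciprocal distances instead.
#' @param net a `signed_network`.
#' @param harmonic use the harmonic variant.
#' @return named numeric vector.
#' @export
closeness <- function(net, harmonic = FALSE) {
  D <- shortest_path_lengths(net)
  diag(D) <- NA
  if (harmonic) {
    v <- rowSums(1 / D, na.rm = TRUE)
  } else {
    v <- apply(D, 1, function(d) {
      d <- d[is.finite(d) & !is.na(d)]
      if (!length(d)) 0 else 1 / sum(d)
    })
  }
  setNames(as.numeric(v), net$nodes$node_id)
}

#' Betweenness centrality
#'
#' Brandes betweenness on `1/|W|` edge lengths with fractional credit for
#' tied shortest paths; each unordered pair counted once.
#' @param net a `signed_network`.
#' @return named numeric vector.
#' @export
betweenness <- function(net) {
  g <- as_igraph(net, absolute = TRUE)
  if (igraph::ecount(g) == 0)
    return(setNames(rep(0, nrow(net$W)), net$nodes$node_id))
  b <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                           directed = FALSE)
  setNames(as.numeric(b), net$nodes$node_id)
}

#' Identify hub nodes
#'
#' Hubs have betweenness more than `k` (sample) standard deviations above
#' the mean: `b_i > mean(b) + k sd(b)`. With zero variance no node is a hub.
#' @param b named betweenness vector (from [betweenness()]).
#' @param k number of standard deviations (default 2).
#' @return character vector of hub node ids.
#' @export
identify_hubs <- function(b, k = 2) {
  if (length(b) < 3) stop("need at least 3 nodes")
  s <- sd(b)
  if (!is.finite(s) || s == 0) return(character())
  names(b)[b > mean(b) + k * s]
}

#' Global connectivity
#'
#' Sum of absolute edge weights over unordered pairs:
#' `sum_(i<j) |W_ij|`.
#' @param net a `signed_network`.
#' @return numeric scalar.
#' @export
global_connectivity <- function(net) sum(abs(net$W[upper.tri(net$W)]))

#' Inter-layer connectivity
#'
#' Sum of |w| over edges with one endpoint in `layerA` and the other in
#' `layerB`; with `layerA == layerB`, the intra-layer sum. Summing over all
#' ordered-once layer pairs recovers [global_connectivity()].
#' @param net a `multilayer_network`.
#' @param layerA,layerB layer names.
#' @return numeric scalar.
#' @export
interlayer_connectivity <- function(net, layerA, layerB) {
  ly <- net$nodes$layer
  for (l in c(layerA, layerB))
    if (!l %in% ly) stop("unknown layer: ", l)
  a <- which(ly == layerA)
  b <- which(ly == layerB)
  if (layerA == layerB) {
    sub <- net$W[a, a, drop = FALSE]
    sum(abs(sub[upper.tri(sub)]))
  } else {
    sum(abs(net$W[a, b, drop = FALSE]))
  }
}

#' Network diameter
#'
#' Maximum finite shortest-path distance. `convention = "invweight"`
#' (default) uses `1/|W|` edge lengths; `"hops"` counts unweighted steps
#' on the edge support.
#' @param net a `signed_network`.
#' @param convention `"invweight"` or `"hops"`.
#' @return numeric scalar (0 for an edgeless network).
#' @export
diameter <- function(net, convention = c("invweight", "hops")) {
  convention <- match.arg(convention)
  if (convention == "invweight") {
    D <- shortest_path_lengths(net)
  } else {
    g <- as_igraph(net, absolute = TRUE)
    D <- igraph::distances(g, weights = NA)
  }
  f <- D[is.finite(D)]
  if (!length(f)) return(0)
  max(f)
}

#' Continuous power-law fit with bootstrap KS test
#'
#' Clauset-Shalizi-Newman procedure for continuous data: for each candidate
#' `x_min`, the tail exponent is the MLE
#' `alpha = 1 + m / sum(log(x / x_min))` and the fit's KS distance to the
#' fitted tail CDF is computed; `x_min` minimizing the KS distance is kept.
#' The p-value comes from a semiparametric bootstrap: each replicate
#' resamples the body empirically and the tail from the fitted power law,
#' refits, and the p-value is the fraction of replicate KS distances at
#' least the observed one (large p = consistent with a power law). Applied
#' by default to node strength ("weighted degree").
#'
#' @param values positive numeric vector (>= 10 values).
#' @param n_boot bootstrap replicates (default 500).
#' @param seed RNG seed.
#' @param xmins candidate x_min values (default: unique observed values).
#' @return list with `alpha`, `xmin`, `ks_stat`, `p_value`, `n_tail`.
#' @export
powerlaw_ks_test <- function(values, n_boot = 500, seed = 1, xmins = NULL) {
  x <- values[is.finite(values) & values > 0]
  if (length(x) < 10) stop("need at least 10 positive values")
  if (length(unique(x)) == 1) stop("all values are equal")
  fit <- .pl_fit(x, xmins)
  with_seed(seed, {
    n <- length(x)
    body <- x[x < fit$xmin]
    p_tail <- fit$n_tail / n
    ks_boot <- vapply(seq_len(n_boot), function(b) {
      tail_n <- rbinom(1, n, p_tail)
      xs <- c(sample(body, n - tail_n, replace = TRUE),
              fit$xmin * runif(tail_n)^(-1 / (fit$alpha - 1)))
      .pl_fit(xs, xmins)$ks
    }, numeric(1))
    list(alpha = fit$alpha, xmin = fit$xmin, ks_stat = fit$ks,
         p_value = mean(ks_boot >= fit$ks), n_tail = fit$n_tail)
  })
}

.pl_fit <- function(x, xmins = NULL) {
  x <- sort(x)
  cand <- if (is.null(xmins)) unique(x) else sort(unique(xmins))
  cand <- cand[cand <= x[length(x) - 4]]  # keep >= 5 tail points
  if (!length(cand)) cand <- x[1]
  best <- list(ks = Inf)
  for (xm in cand) {
    tail <- x[x >= xm]
    m <- length(tail)
    sl <- sum(log(tail / xm))
    if (sl <= 0) next
    alpha <- 1 + m / sl
    emp <- (seq_len(m) - 1) / m
    theo <- 1 - (tail / xm)^(1 - alpha)
    ks <- max(abs(emp - theo), abs(emp + 1 / m - theo))
    if (ks < best$ks)
      best <- list(alpha = alpha, xmin = xm, ks = ks, n_tail = m)
  }
  if (!is.finite(best$ks)) stop("power-law fit failed")
  best
}

#' Per-node centrality table
#'
#' Strength, closeness, betweenness and expected influence per node with
#' z-scored variants and the hub flag (betweenness > mean + 2 sd).
#' @param net a `signed_network` or `multilayer_network`.
#' @param hub_k hub threshold in standard deviations (default 2).
#' @return data frame, one row per node.
#' @export
centrality_table <- function(net, hub_k = 2) {
  b <- betweenness(net)
  hubs <- identify_hubs(b, k = hub_k)
  zs <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  s <- strength(net); cl <- closeness(net); ei <- expected_influence(net)
  data.frame(node_id = net$nodes$node_id, layer = net$nodes$layer,
             strength = as.numeric(s), closeness = as.numeric(cl),
             betweenness = as.numeric(b), expected_influence = as.numeric(ei),
             z_strength = zs(as.numeric(s)), z_closeness = zs(as.numeric(cl)),
             z_betweenness = zs(as.numeric(b)),
             z_expected_influence = zs(as.numeric(ei)),
             hub_flag = net$nodes$node_id %in% hubs,
             stringsAsFactors = FALSE)
}

#' Network-level topology summary
#'
#' Global connectivity, all pairwise inter-layer connectivities, diameter,
#' and the power-law fit of node strength.
#' @param net a `multilayer_network`.
#' @param n_boot bootstrap replicates for the power-law test.
#' @param seed RNG seed for the bootstrap.
#' @return list (`topology_summary`).
#' @export
topology_summary <- function(net, n_boot = 200, seed = 1) {
  layers <- unique(net$nodes$layer)
  pairs <- t(combn(layers, 2))
  inter <- apply(pairs, 1, function(pr)
    interlayer_connectivity(net, pr[1], pr[2]))
  names(inter) <- paste(pairs[, 1], pairs[, 2], sep = "~")
  s <- strength(net)
  pl <- tryCatch(powerlaw_ks_test(s[s > 0], n_boot = n_boot, seed = seed),
                 error = function(e) list(alpha = NA, ks_stat = NA,
                                          p_value = NA))
  list(global_connectivity = global_connectivity(net),
       interlayer_connectivity = as.list(inter),
       diameter = diameter(net),
       ks_statistic = pl$ks_stat, ks_pvalue = pl$p_value,
       powerlaw_alpha = pl$alpha)
}
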