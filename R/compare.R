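# Two-group network comparison: median split by activity, permutation test
# with full re-estimation inside every permutation, Holm-Bonferroni control.

#' Median split by physical activity
#'
#' Subjects strictly above the median go to the high-activity group,
#' subjects at or below the median to the low group (ties at the median
#' are assigned low).
#'
#' @param activity per-subject numeric counts (names used as ids if
#'   present; otherwise indices are returned).
#' @return list with `high`, `low` (ids or indices) and `median`.
#' @export
median_split <- function(activity) {
  keep <- !is.na(activity)
  if (sum(keep) < 2) stop("need >= 2 subjects with non-missing activity")
  ids <- names(activity) %||% seq_along(activity)
  ids <- ids[keep]; act <- activity[keep]
  if (length(unique(act)) == 1) stop("all activity values identical")
  m <- median(act)
  list(high = ids[act > m], low = ids[act <= m], median = m)
}

# one full estimation pass: npn -> pairwise correlation -> EBIC glasso -> W
.estimate_W <- function(X, gamma = 0.5, n_lambda = 100,
                        lambda_min_ratio = 0.01) {
  Xn <- nonparanormal_transform(X)
  pc <- suppressMessages(pairwise_complete_correlation(Xn))
  fit <- select_model(pc$R, pc$n_effective, gamma = gamma,
                      n_lambda = n_lambda,
                      lambda_min_ratio = lambda_min_ratio)
  to_partial_correlations(selected_precision(fit))
}

.compare_stats <- function(Wa, Wb, node_meta, edge_idx) {
  neta <- multilayer_network(signed_network(Wa, node_meta))
  netb <- multilayer_network(signed_network(Wb, node_meta))
  cs <- function(net) c(strength = strength(net), closeness = closeness(net),
                        betweenness = betweenness(net),
                        expected_influence = expected_influence(net))
  layers <- unique(node_meta$layer)
  il <- function(net) {
    if (length(layers) < 2) return(numeric())
    pr <- t(combn(layers, 2))
    setNames(apply(pr, 1, function(x)
      interlayer_connectivity(net, x[1], x[2])),
      paste(pr[, 1], pr[, 2], sep = "~"))
  }
  list(global = global_connectivity(neta) - global_connectivity(netb),
       edges = (Wa - Wb)[edge_idx, drop = FALSE],
       centrality = cs(neta) - cs(netb),
       interlayer = il(neta) - il(netb))
}

#' Permutation network comparison test
#'
#' Networks are estimated independently in each group through the full
#' pipeline (nonparanormal transform, pairwise-complete correlation,
#' EBIC-glasso) and their differences in global connectivity, edge
#' weights, node centralities and inter-layer connectivity are referred
#' to a permutation null built by pooling subjects, reshuffling group
#' labels preserving group sizes, and re-running the full estimation for
#' every permutation. Two-sided p-values use absolute differences with
#' the +1 correction `p = (1 + #(perm >= obs)) / (n_perm + 1)`. Edge
#' tests cover all node pairs in the union support of the two observed
#' networks and are Holm-corrected as one family; centrality differences
#' form a second family and inter-layer differences a third.
#'
#' @param Xa,Xb subject-by-variable matrices (raw/centered scale; the
#'   nonparanormal transform is applied internally), same columns.
#' @param node_meta node metadata matching the columns.
#' @param n_perm number of permutations (default 1000; scale up for
#'   publication-grade inference).
#' @param alpha family-wise error level for Holm decisions.
#' @param gamma,n_lambda,lambda_min_ratio estimation settings.
#' @param seed RNG seed (permutations are deterministic given it).
#' @return object of class `comparison_result` with observed statistics,
#'   p-values, Holm-adjusted p-values/decisions, the two estimated
#'   networks, and bookkeeping (`n_perm`, `seed`, failed-permutation
#'   count).
#' @export
nct <- function(Xa, Xb, node_meta, n_perm = 1000, alpha = 0.05,
                gamma = 0.5, n_lambda = 100, lambda_min_ratio = 0.01,
                seed = 1) {
  stopifnot(identical(colnames(Xa), colnames(Xb)))
  node_meta <- node_meta[match(colnames(Xa), node_meta$node_id), ,
                         drop = FALSE]
  est <- function(X) .estimate_W(X, gamma, n_lambda, lambda_min_ratio)
  Wa <- est(Xa); Wb <- est(Xb)
  support <- (abs(Wa) > 0 | abs(Wb) > 0) & upper.tri(Wa)
  edge_idx <- which(support, arr.ind = TRUE)
  obs <- .compare_stats(Wa, Wb, node_meta, edge_idx)
  pool <- rbind(Xa, Xb)
  na <- nrow(Xa); n <- nrow(pool)
  exceed <- lapply(obs, function(x) x * 0)
  nfail <- 0L
  with_seed(seed, {
    b <- 0L
    while (b < n_perm) {
      ia <- sample.int(n, na)
      st <- tryCatch(
        .compare_stats(est(pool[ia, , drop = FALSE]),
                       est(pool[-ia, , drop = FALSE]), node_meta, edge_idx),
        error = function(e) NULL)
      if (is.null(st)) {
        nfail <- nfail + 1L
        if (nfail > max(1, ceiling(0.01 * n_perm)))
          stop("more than 1% of permutations failed estimation")
        next
      }
      b <- b + 1L
      for (k in names(exceed))
        exceed[[k]] <- exceed[[k]] + (abs(st[[k]]) >= abs(obs[[k]]) - 1e-12)
    }
  })
  pval <- lapply(exceed, function(x) (1 + x) / (n_perm + 1))
  ids <- node_meta$node_id
  edges <- data.frame(from = ids[edge_idx[, 1]], to = ids[edge_idx[, 2]],
                      w_a = Wa[edge_idx], w_b = Wb[edge_idx],
                      diff = obs$edges, p = as.numeric(pval$edges),
                      stringsAsFactors = FALSE)
  hb_e <- holm_bonferroni(edges$p, alpha)
  edges$p_holm <- hb_e$p_adjusted
  edges$reject <- hb_e$reject
  hb_c <- holm_bonferroni(as.numeric(pval$centrality), alpha)
  centrality <- data.frame(statistic = names(obs$centrality),
                           diff = as.numeric(obs$centrality),
                           p = as.numeric(pval$centrality),
                           p_holm = hb_c$p_adjusted, reject = hb_c$reject,
                           stringsAsFactors = FALSE)
  interlayer <- NULL
  if (length(obs$interlayer)) {
    hb_i <- holm_bonferroni(as.numeric(pval$interlayer), alpha)
    interlayer <- data.frame(layer_pair = names(obs$interlayer),
                             diff = as.numeric(obs$interlayer),
                             p = as.numeric(pval$interlayer),
                             p_holm = hb_i$p_adjusted, reject = hb_i$reject,
                             stringsAsFactors = FALSE)
  }
  structure(list(
    global = list(diff = obs$global, p = pval$global),
    edges = edges, centrality = centrality, interlayer = interlayer,
    network_a = multilayer_network(signed_network(Wa, node_meta, nrow(Xa))),
    network_b = multilayer_network(signed_network(Wb, node_meta, nrow(Xb))),
    n_perm = n_perm, alpha = alpha, seed = seed, n_failed = nfail),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "comparison_result: %d permutations (seed %s)\n  global connectivity diff = %.4f (p = %.4f)\n  %d edge tests, %d Holm-significant\n",
    x$n_perm, x$seed, x$global$diff, x$global$p, nrow(x$edges),
    sum(x$edges$reject)))
  invisible(x)
}

#' Holm-Bonferroni step-down correction
#'
#' Sorted ascending, `p_(k)` is rejected while `p_(k) <= alpha/(m-k+1)`;
#' the first failure stops the procedure. Decisions are mapped back to the
#' input order; adjusted p-values are the standard step-down monotone
#' cummax.
#'
#' @param p_values numeric p-values in (0, 1].
#' @param alpha family-wise error rate (default 0.05).
#' @return list with `reject` (logical) and `p_adjusted`.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (!length(p_values))
    return(list(reject = logical(), p_adjusted = numeric()))
  adj <- p.adjust(p_values, method = "holm")
  list(reject = adj <= alpha, p_adjusted = adj)
}
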