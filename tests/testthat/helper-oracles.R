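# Independent brute-force oracles used to validate the package's
# implementations. These deliberately avoid the code paths they check:
# shortest paths by Floyd-Warshall, betweenness by exhaustive path
# enumeration, the glasso objective by proximal-gradient descent.

# all-pairs shortest paths on 1/|W| lengths, Floyd-Warshall
oracle_distances <- function(W) {
  p <- nrow(W)
  D <- matrix(Inf, p, p)
  diag(D) <- 0
  for (i in seq_len(p)) for (j in seq_len(p))
    if (i != j && abs(W[i, j]) > 0) D[i, j] <- 1 / abs(W[i, j])
  for (k in seq_len(p)) for (i in seq_len(p)) for (j in seq_len(p))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# enumerate all simple paths i -> j, return those of minimal length
oracle_shortest_paths <- function(W, from, to) {
  p <- nrow(W)
  paths <- list()
  walk <- function(path, len) {
    v <- path[length(path)]
    if (v == to) {
      paths[[length(paths) + 1]] <<- list(path = path, len = len)
      return()
    }
    for (u in seq_len(p)) {
      if (abs(W[v, u]) > 0 && !(u %in% path))
        walk(c(path, u), len + 1 / abs(W[v, u]))
    }
  }
  walk(from, 0)
  if (!length(paths)) return(list())
  lens <- vapply(paths, `[[`, numeric(1), "len")
  paths[lens < min(lens) + 1e-10]
}

# Brandes-style betweenness by exhaustive enumeration (fractional credit)
oracle_betweenness <- function(W) {
  p <- nrow(W)
  b <- numeric(p)
  for (s in seq_len(p - 1)) for (t in (s + 1):p) {
    sp <- oracle_shortest_paths(W, s, t)
    if (!length(sp)) next
    for (path in sp) {
      inner <- setdiff(path$path, c(s, t))
      b[inner] <- b[inner] + 1 / length(sp)
    }
  }
  b
}

oracle_closeness <- function(W) {
  D <- oracle_distances(W)
  diag(D) <- NA
  apply(D, 1, function(d) {
    d <- d[is.finite(d) & !is.na(d)]
    if (!length(d)) 0 else 1 / sum(d)
  })
}

# triangle census by direct triple enumeration
oracle_balance <- function(W) {
  p <- nrow(W)
  if (p < 3) return(c(n = 0, balanced = 0))
  trip <- combn(p, 3)
  n <- 0; bal <- 0
  for (k in seq_len(ncol(trip))) {
    i <- trip[1, k]; j <- trip[2, k]; l <- trip[3, k]
    if (abs(W[i, j]) > 0 && abs(W[i, l]) > 0 && abs(W[j, l]) > 0) {
      n <- n + 1
      if (W[i, j] * W[i, l] * W[j, l] > 0) bal <- bal + 1
    }
  }
  c(n = n, balanced = bal)
}

oracle_transitivity <- function(W) {
  A <- abs(W) > 0
  p <- nrow(W)
  closed <- 0; triples <- 0
  for (v in seq_len(p)) {
    nb <- which(A[v, ])
    if (length(nb) < 2) next
    prs <- combn(nb, 2)
    triples <- triples + ncol(prs)
    for (k in seq_len(ncol(prs)))
      if (A[prs[1, k], prs[2, k]]) closed <- closed + 1
  }
  if (triples == 0) return(0)
  closed / triples
}

# proximal-gradient (ISTA) solver for the glasso objective
#   min -log det(Theta) + tr(R Theta) + lambda ||Theta||_{1,off}
oracle_glasso_ista <- function(R, lambda, maxit = 50000, tol = 1e-10) {
  p <- nrow(R)
  soft_off <- function(M, t) {
    S <- sign(M) * pmax(abs(M) - t, 0)
    diag(S) <- diag(M)
    S
  }
  Theta <- diag(1 / diag(R))
  step <- 0.1
  fval <- function(Th) {
    ev <- eigen(Th, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(Inf)
    -sum(log(ev)) + sum(R * Th) + lambda * (sum(abs(Th)) - sum(abs(diag(Th))))
  }
  f_old <- fval(Theta)
  for (it in seq_len(maxit)) {
    G <- R - solve(Theta)
    t_k <- step
    repeat {
      Cand <- soft_off(Theta - t_k * G, t_k * lambda)
      f_new <- fval(Cand)
      if (is.finite(f_new) && f_new <= f_old + 1e-14) break
      t_k <- t_k / 2
      if (t_k < 1e-12) break
    }
    delta <- max(abs(Cand - Theta))
    Theta <- Cand
    f_old <- f_new
    if (delta < tol) break
  }
  (Theta + t(Theta)) / 2
}

# random SPD correlation matrix (random factor structure)
random_correlation <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) + diag(p) * 0.5
  D <- sqrt(diag(S))
  S / tcrossprod(D)
}

# random connected signed network on p nodes
random_signed_network <- function(p, seed, edge_prob = 0.5) {
  set.seed(seed)
  repeat {
    W <- matrix(0, p, p)
    ut <- upper.tri(W)
    n_e <- sum(ut)
    w <- ifelse(runif(n_e) < edge_prob,
                runif(n_e, 0.1, 0.9) * sign(runif(n_e) - 0.3), 0)
    W[ut] <- w
    W <- W + t(W)
    # connectivity check via reachability
    A <- abs(W) > 0
    reach <- A | diag(p)
    for (k in seq_len(p)) reach <- reach | (reach %*% reach > 0)
    if (all(reach)) break
    seed <- seed + 1000
    set.seed(seed)
  }
  W
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# F1 of estimated vs true edge support
edge_f1 <- function(W_est, W_true) {
  ut <- upper.tri(W_true)
  e <- abs(W_est[ut]) > 0
  t <- abs(W_true[ut]) > 0
  tp <- sum(e & t)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + sum(e & !t) + sum(!e & t))
}

# sample n rows from N(0, solve(Theta)) with named columns
sample_mvn_precision <- function(Theta, n, seed) {
  set.seed(seed)
  L <- chol(chol2inv(chol(Theta)))
  X <- matrix(rnorm(n * nrow(Theta)), n) %*% L
  colnames(X) <- colnames(Theta)
  X
}

# small two-layer study model with an optional planted group-unique edge
# (partial correlation -0.4 between S05 and P01), used in the permutation
# comparison experiments
mini_study_theta <- function(planted = FALSE) {
  ids <- c(sprintf("S%02d", 1:6), sprintf("P%02d", 1:4))
  p <- length(ids)
  Th <- matrix(0, p, p, dimnames = list(ids, ids))
  set.seed(7)
  for (i in 1:5) Th[i, i + 1] <- -runif(1, 1.2, 2)
  for (i in 7:9) Th[i, i + 1] <- -runif(1, 1.2, 2)
  Th[2, 8] <- -1
  Th <- Th + t(Th)
  if (planted) {
    i <- 5; j <- 7
    bi <- 1 + sum(abs(Th[i, ])); bj <- 1 + sum(abs(Th[j, ]))
    x <- 0.4
    for (k in 1:25) x <- 0.4 * sqrt((bi + x) * (bj + x))
    Th[i, j] <- Th[j, i] <- x
  }
  diag(Th) <- 1 + rowSums(abs(Th))
  Th
}

mini_study_meta <- function() {
  ids <- c(sprintf("S%02d", 1:6), sprintf("P%02d", 1:4))
  data.frame(node_id = ids,
             layer = rep(c("synaptic_peptide", "pathological_peptide"),
                         c(6, 4)),
             stringsAsFactors = FALSE)
}
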