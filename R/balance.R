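# Structural balance: signed triangle census on the estimated graph's
# support. A triangle is balanced iff the product of its three edge signs
# is positive (e.g. + - - balanced, + + - unbalanced).

#' Enumerate closed triangles
#'
#' All unordered node triples whose three pairwise edges are present
#' (|W| > 0).
#' @param net a `signed_network`.
#' @return integer matrix with columns `i`, `j`, `k` (node indices,
#'   i < j < k); zero rows when there are none.
#' @export
enumerate_triangles <- function(net) {
  A <- abs(net$W) > 0
  p <- nrow(A)
  out <- list()
  for (i in seq_len(max(p - 2, 0))) {
    ni <- which(A[i, ] & seq_len(p) > i)
    if (length(ni) < 2) next
    for (a in seq_len(length(ni) - 1)) for (b in (a + 1):length(ni)) {
      j <- ni[a]; k <- ni[b]
      if (A[j, k]) out[[length(out) + 1]] <- c(i, j, k)
    }
  }
  if (!length(out))
    return(matrix(integer(), 0, 3, dimnames = list(NULL, c("i", "j", "k"))))
  m <- do.call(rbind, out)
  colnames(m) <- c("i", "j", "k")
  m
}

#' Is a signed triangle balanced?
#'
#' Balanced iff the product of the three edge signs is positive.
#' @param sign_a,sign_b,sign_c edge signs (+1 or -1; vectors allowed).
#' @return logical.
#' @export
is_balanced <- function(sign_a, sign_b, sign_c) {
  s <- cbind(sign_a, sign_b, sign_c)
  if (any(s == 0)) stop("zero sign: an absent edge cannot form a triangle")
  as.vector(sign_a * sign_b * sign_c > 0)
}

#' Global structural balance
#'
#' Fraction of balanced triangles among all closed triangles, with the
#' full list of unbalanced triangles for motif inspection.
#' @param net a `signed_network`.
#' @return object of class `balance_result`: `n_triangles`, `n_balanced`,
#'   `balance_fraction` (NA with a warning when no triangle exists),
#'   `triangles` (data frame with node ids, signs, weights, balanced flag),
#'   `unbalanced` (subset).
#' @export
global_balance <- function(net) {
  tri <- enumerate_triangles(net)
  ids <- net$nodes$node_id
  if (nrow(tri) == 0) {
    warning("no closed triangles; balance fraction undefined")
    tt <- data.frame(a = character(), b = character(), c = character(),
                     w_ab = numeric(), w_ac = numeric(), w_bc = numeric(),
                     balanced = logical())
    return(structure(list(n_triangles = 0L, n_balanced = 0L,
                          balance_fraction = NA_real_, triangles = tt,
                          unbalanced = tt), class = "balance_result"))
  }
  W <- net$W
  w_ab <- W[tri[, c("i", "j"), drop = FALSE]]
  w_ac <- W[tri[, c("i", "k"), drop = FALSE]]
  w_bc <- W[tri[, c("j", "k"), drop = FALSE]]
  bal <- is_balanced(sign(w_ab), sign(w_ac), sign(w_bc))
  tt <- data.frame(a = ids[tri[, 1]], b = ids[tri[, 2]], c = ids[tri[, 3]],
                   w_ab = w_ab, w_ac = w_ac, w_bc = w_bc, balanced = bal,
                   stringsAsFactors = FALSE)
  structure(list(n_triangles = nrow(tt), n_balanced = sum(bal),
                 balance_fraction = mean(bal), triangles = tt,
                 unbalanced = tt[!tt$balanced, , drop = FALSE]),
            class = "balance_result")
}

#' @export
print.balance_result <- function(x, ...) {
  cat(sprintf("balance_result: %d triangles, %d balanced (B = %s)\n",
              x$n_triangles, x$n_balanced,
              ifelse(is.na(x$balance_fraction), "NA",
                     sprintf("%.3f", x$balance_fraction))))
  invisible(x)
}

#' Triangles containing given nodes
#'
#' All closed triangles with at least one endpoint among `node_ids`,
#' labeled balanced/unbalanced with edge weights (for inspecting
#' unbalanced motifs around named hubs).
#' @param net a `signed_network`.
#' @param node_ids character vector of node ids.
#' @return data frame in the format of `global_balance(net)$triangles`.
#' @export
triangles_containing <- function(net, node_ids) {
  unknown <- setdiff(node_ids, net$nodes$node_id)
  if (length(unknown))
    stop("unknown node id(s): ", paste(unknown, collapse = ", "))
  tt <- suppressWarnings(global_balance(net)$triangles)
  tt[tt$a %in% node_ids | tt$b %in% node_ids | tt$c %in% node_ids, ,
     drop = FALSE]
}
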