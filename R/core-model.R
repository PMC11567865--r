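#' Network layers recognized by the multilayer model
#'
#' The four layers are: 48 synaptic peptides (SRM light:heavy ratios),
#' 4 SNARE protein-protein interaction measures, 14 pathological
#' (amyloid/tau) peptides, and 5 cellular pathology densities.
#' @export
LAYERS <- c("synaptic_peptide", "ppi_complex", "pathological_peptide",
            "cellular_pathology")

# numerical edge-presence threshold: entries below this are treated as absent
EDGE_EPS <- 1e-12

#' Construct a signed weighted network
#'
#' A signed network holds a symmetric matrix of partial correlations with
#' zero diagonal, one row/column per node. Node metadata rows are matched
#' to matrix rows by position; `node_id` must be unique.
#'
#' @param W symmetric p x p numeric matrix of signed edge weights in \[-1, 1\].
#' @param nodes data frame of node metadata with at least columns `node_id`
#'   and `layer`; optional `label`, `function_tag`, `cell_type`,
#'   `localization`, `module_id`.
#' @param n_samples effective sample size used at estimation.
#' @return object of class `signed_network`.
#' @export
signed_network <- function(W, nodes, n_samples = NA_integer_) {
  W <- as.matrix(W)
  if (is.character(nodes)) nodes <- data.frame(node_id = nodes)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$node_id)) stop("nodes must carry a node_id column")
  if (is.null(nodes$layer)) nodes$layer <- NA_character_
  if (is.null(nodes$label)) nodes$label <- nodes$node_id
  dimnames(W) <- list(nodes$node_id, nodes$node_id)
  W[abs(W) < EDGE_EPS] <- 0
  structure(list(W = W, nodes = nodes, n_samples = n_samples),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  p <- nrow(x$W)
  ne <- sum(abs(x$W[upper.tri(x$W)]) > 0)
  cat(sprintf("%s: %d nodes, %d edges (%d negative), n = %s\n",
              class(x)[1], p, ne, sum(x$W[upper.tri(x$W)] < 0),
              ifelse(is.na(x$n_samples), "?", x$n_samples)))
  invisible(x)
}

#' Construct a multilayer network
#'
#' Wraps a [signed_network()] with a node-to-layer assignment. An edge is
#' intra-layer when both endpoints share a layer, inter-layer otherwise.
#'
#' @param network a `signed_network` whose nodes all have a `layer` entry.
#' @return object of class `multilayer_network` (inherits `signed_network`).
#' @export
multilayer_network <- function(network) {
  stopifnot(inherits(network, "signed_network"))
  if (anyNA(network$nodes$layer)) stop("every node needs a layer")
  bad <- setdiff(unique(network$nodes$layer), LAYERS)
  if (length(bad)) stop("unknown layer(s): ", paste(bad, collapse = ", "))
  class(network) <- c("multilayer_network", "signed_network")
  network
}

#' @export
print.multilayer_network <- function(x, ...) {
  NextMethod()
  tab <- table(factor(x$nodes$layer, levels = LAYERS))
  cat("  layers:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

layer_of <- function(net) setNames(net$nodes$layer, net$nodes$node_id)

#' Validate signed-network invariants
#'
#' Checks symmetry (to 1e-12), zero diagonal, weight bound |w| <= 1,
#' node/matrix dimension agreement and node-id uniqueness. Validation
#' never raises; it returns descriptions of the violations found.
#'
#' @param net a `signed_network`.
#' @return character vector of human-readable violations; empty if valid.
#' @export
validate_network <- function(net) {
  v <- character()
  W <- net$W
  p <- nrow(W)
  if (p != nrow(net$nodes))
    v <- c(v, sprintf("matrix has %d rows but %d nodes", p, nrow(net$nodes)))
  if (anyDuplicated(net$nodes$node_id))
    v <- c(v, "duplicate node_id")
  asym <- which(abs(W - t(W)) > 1e-12, arr.ind = TRUE)
  if (nrow(asym))
    v <- c(v, sprintf("asymmetry at (%d,%d)", asym[1, 1] - 1L, asym[1, 2] - 1L))
  dg <- which(abs(diag(W)) > 0)
  if (length(dg))
    v <- c(v, sprintf("nonzero diagonal at %d", dg[1] - 1L))
  ob <- which(abs(W) > 1 + 1e-12, arr.ind = TRUE)
  if (nrow(ob))
    v <- c(v, sprintf("weight out of [-1,1] at (%d,%d)", ob[1, 1] - 1L, ob[1, 2] - 1L))
  v
}

#' Extract a subnetwork by node ids
#'
#' Returns the induced subnetwork on `keep`: the corresponding rows/columns
#' of the weight matrix. Node order follows the parent network's order. Note
#' this is extraction only; re-estimating a layer-restricted model is done
#' with [select_model()] on the corresponding data columns.
#'
#' @param net a `signed_network` or `multilayer_network`.
#' @param keep character vector of node ids to retain.
#' @return a network of the same class on the kept nodes.
#' @export
subnetwork <- function(net, keep) {
  unknown <- setdiff(keep, net$nodes$node_id)
  if (length(unknown))
    stop("unknown node id(s): ", paste(unknown, collapse = ", "))
  idx <- which(net$nodes$node_id %in% keep)
  out <- signed_network(net$W[idx, idx, drop = FALSE],
                        net$nodes[idx, , drop = FALSE], net$n_samples)
  if (inherits(net, "multilayer_network")) out <- multilayer_network(out)
  out
}

#' Edge list of a network
#'
#' One record per unordered node pair with nonzero weight. For multilayer
#' networks each edge is classified `intra` (both endpoints in the same
#' layer) or `inter`.
#'
#' @param net a `signed_network` or `multilayer_network`.
#' @return data frame with columns `from`, `to`, `weight` and, when layers
#'   are known, `type`.
#' @export
edge_list <- function(net) {
  W <- net$W
  ut <- upper.tri(W)
  idx <- which(ut & abs(W) > 0, arr.ind = TRUE)
  ids <- net$nodes$node_id
  out <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                    weight = W[idx], stringsAsFactors = FALSE)
  if (!anyNA(net$nodes$layer)) {
    ly <- net$nodes$layer
    out$type <- ifelse(ly[idx[, 1]] == ly[idx[, 2]], "intra", "inter")
  }
  out[order(out$from, out$to), , drop = FALSE]
}

#' Convert a network to an igraph graph
#'
#' Edge attribute `weight` keeps the signed partial correlation; node
#' attributes carry layer and module assignments when present.
#'
#' @param net a `signed_network`.
#' @param absolute use |w| as the weight (for layout/shortest paths).
#' @return an `igraph` object.
#' @export
as_igraph <- function(net, absolute = FALSE) {
  W <- net$W
  if (absolute) W <- abs(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- net$nodes$node_id
  if (!anyNA(net$nodes$layer)) igraph::V(g)$layer <- net$nodes$layer
  if (!is.null(net$nodes$module_id)) igraph::V(g)$module <- net$nodes$module_id
  g
}

#' Write a network as GraphML and a flat CSV edge list
#'
#' @param net a `signed_network`.
#' @param graphml_path,csv_path output file paths (either may be `NULL`).
#' @return invisibly, the edge list written.
#' @export
write_network <- function(net, graphml_path = NULL, csv_path = NULL) {
  el <- edge_list(net)
  if (!is.null(graphml_path))
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  if (!is.null(csv_path))
    write.csv(el, csv_path, row.names = FALSE)
  invisible(el)
}

#' Read node metadata from TSV
#'
#' Expected columns: `node_id`, `label`, `layer` and optionally
#' `function_tag`, `cell_type`, `localization`.
#'
#' @param path TSV file path.
#' @return data frame of node metadata.
#' @export
read_node_meta <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_id", "layer")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("node metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(meta$node_id)) stop("duplicate node_id in metadata")
  bad <- setdiff(unique(meta$layer), LAYERS)
  if (length(bad)) stop("unknown layer(s): ", paste(bad, collapse = ", "))
  meta
}
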