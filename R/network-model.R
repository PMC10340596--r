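## Undirected weighted network over the 8 continuous subscale nodes plus
## the dichotomous child-sex node, for one role x time stratum.
## Continuous-continuous edges carry the sign of the underlying partial
## association; edges touching the dichotomous node are unsigned
## presence/absence but keep their magnitude for path computations.

#' Construct a network model
#'
#' @param weights Symmetric numeric matrix with zero diagonal. For edges
#'   between two continuous nodes the entry is the signed standardized
#'   weight; for edges involving the dichotomous node the magnitude is
#'   stored (sign is not interpreted).
#' @param labels Node labels; default [network_node_labels()].
#' @param node_types Character vector, `"continuous"` or `"categorical"`
#'   per node.
#' @param parent_role,time_point Stratum tag (may be `NA` for synthetic or
#'   ad hoc networks).
#' @param n Sample size behind the estimate.
#' @param unstable Data frame of node pairs dropped for sign conflict
#'   between the two nodewise regressions (may be empty).
#' @param edge_support Optional symmetric matrix of bootstrap inclusion
#'   proportions in `[0,1]`; `NA` when no bootstrap has been run. Edges with
#'   support below 0.5 are flagged non-significant ("gray") on export.
#' @return A `network_model` object.
#' @export
network_model <- function(weights,
                          labels = network_node_labels(),
                          node_types = c(rep("continuous", 8), "categorical"),
                          parent_role = NA_character_,
                          time_point = NA_character_,
                          n = NA_integer_,
                          unstable = NULL,
                          edge_support = NULL) {
  weights <- as.matrix(weights)
  p <- length(labels)
  stopifnot(nrow(weights) == p, ncol(weights) == p,
            length(node_types) == p)
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 0,
                        check.attributes = FALSE))) {
    stop("weights matrix must be exactly symmetric")
  }
  if (any(diag(weights) != 0)) stop("weights diagonal must be zero")
  dimnames(weights) <- list(labels, labels)
  if (is.null(unstable)) {
    unstable <- data.frame(node_i = character(0), node_j = character(0))
  }
  if (!is.null(edge_support)) {
    edge_support <- as.matrix(edge_support)
    dimnames(edge_support) <- list(labels, labels)
  }
  structure(
    list(labels = labels, weights = weights, node_types = node_types,
         parent_role = parent_role, time_point = time_point, n = n,
         unstable = unstable, edge_support = edge_support),
    class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("<network_model> ", x$parent_role, " ", x$time_point,
      ": ", length(x$labels), " nodes, ", ne, " edges, n = ", x$n, "\n",
      sep = "")
  invisible(x)
}

edge_kind <- function(net, i, j) {
  if (net$node_types[i] == "continuous" && net$node_types[j] == "continuous")
    "signed_continuous" else "unsigned_mixed"
}

network_edge_list <- function(net) {
  p <- length(net$labels)
  idx <- which(upper.tri(net$weights) & net$weights != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0), sign = integer(0),
                      kind = character(0), significant = logical(0)))
  }
  kinds <- vapply(seq_len(nrow(idx)),
                  function(r) edge_kind(net, idx[r, 1], idx[r, 2]),
                  character(1))
  w <- net$weights[idx]
  sgn <- ifelse(kinds == "signed_continuous", sign(w), NA_integer_)
  supp <- if (is.null(net$edge_support)) rep(NA_real_, nrow(idx)) else
    net$edge_support[idx]
  data.frame(
    from = net$labels[idx[, 1]],
    to = net$labels[idx[, 2]],
    weight = w,
    sign = as.integer(sgn),
    kind = kinds,
    significant = ifelse(is.na(supp), NA, supp >= 0.5)
  )
}

#' Export a network to GraphML and plain-text edge/node CSV files
#'
#' Writes `<prefix>.graphml` (via igraph, nodes with label/type attributes,
#' edges with weight/sign/kind/significant attributes), `<prefix>_edges.csv`
#' and `<prefix>_nodes.csv`. Weights in the CSV are printed with 17
#' significant digits so that [import_network()] reproduces the weight
#' matrix exactly.
#'
#' @param net A `network_model`.
#' @param prefix Output path prefix (no extension).
#' @param node_size Optional named numeric vector of relative node sizes
#'   (see [node_size_scale()]); defaults to 1 for every node.
#' @return Character vector of the files written, invisibly.
#' @export
export_network <- function(net, prefix, node_size = NULL) {
  el <- network_edge_list(net)
  if (is.null(node_size)) {
    node_size <- setNames(rep(1, length(net$labels)), net$labels)
  }
  nodes <- data.frame(node = net$labels, type = net$node_types,
                      size = as.numeric(node_size[net$labels]))
  g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = nodes)
  files <- paste0(prefix, c(".graphml", "_edges.csv", "_nodes.csv"))
  igraph::write_graph(g, files[1], format = "graphml")
  el_out <- el
  el_out$weight <- formatC(el$weight, digits = 17, format = "g")
  write.csv(el_out, files[2], row.names = FALSE, quote = FALSE)
  write.csv(nodes, files[3], row.names = FALSE, quote = FALSE)
  invisible(files)
}

#' Import a network written by [export_network()]
#'
#' Reads the `_edges.csv`/`_nodes.csv` pair; the reconstructed weight
#' matrix equals the exported one exactly.
#'
#' @param prefix Path prefix used at export time.
#' @return A `network_model`.
#' @export
import_network <- function(prefix) {
  nodes <- read.csv(paste0(prefix, "_nodes.csv"))
  el <- read.csv(paste0(prefix, "_edges.csv"))
  p <- nrow(nodes)
  W <- matrix(0, p, p, dimnames = list(nodes$node, nodes$node))
  S <- matrix(NA_real_, p, p, dimnames = list(nodes$node, nodes$node))
  if (nrow(el) > 0) {
    for (r in seq_len(nrow(el))) {
      i <- match(el$from[r], nodes$node)
      j <- match(el$to[r], nodes$node)
      W[i, j] <- W[j, i] <- el$weight[r]
      if (!is.na(el$significant[r])) {
        S[i, j] <- S[j, i] <- if (el$significant[r]) 1 else 0
      }
    }
  }
  network_model(W, labels = nodes$node, node_types = nodes$type,
                edge_support = if (all(is.na(S))) NULL else S)
}
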