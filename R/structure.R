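## Community structure and plotting geometry. Walks, modularity and
## layouts all use edge magnitudes |w| only; signs matter for rendering
## (green positive / red negative), not for topology.

#' Walktrap community detection
#'
#' Agglomerative clustering of `t`-step random-walk distances computed on
#' the absolute weight matrix, merged by the Ward-style criterion of the
#' original walktrap formulation and cut at the dendrogram level of
#' maximum modularity. Nodes of an edgeless graph are singleton
#' communities.
#'
#' @param net A [network_model()].
#' @param t Walk length (default 4).
#' @return A `cluster_assignment`: `membership` (named integer vector),
#'   `merges` (merge matrix), `modularity_by_level`, `chosen_level`,
#'   `n_communities`, `modularity`.
#' @export
walktrap_cluster <- function(net, t = 4) {
  stopifnot(t >= 1)
  g <- net_to_igraph(net)
  labels <- net$labels
  if (igraph::ecount(g) == 0) {
    membership <- setNames(seq_along(labels), labels)
    return(structure(list(membership = membership,
                          merges = matrix(numeric(0), 0, 2),
                          modularity_by_level = 0,
                          chosen_level = 1L,
                          n_communities = length(labels),
                          modularity = 0),
                     class = "cluster_assignment"))
  }
  wt <- igraph::cluster_walktrap(g, steps = t,
                                 weights = igraph::E(g)$weight)
  membership <- setNames(as.integer(igraph::membership(wt)), labels)
  structure(list(membership = membership,
                 merges = wt$merges,
                 modularity_by_level = wt$modularity,
                 chosen_level = which.max(wt$modularity),
                 n_communities = length(unique(membership)),
                 modularity = max(wt$modularity)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", x$n_communities, " communities, Q = ",
      format(x$modularity, digits = 4), "\n", sep = "")
  print(x$membership)
  invisible(x)
}

#' Newman weighted modularity of a partition
#'
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` over communities `c`, where `e_c`
#' is the total absolute weight inside `c`, `d_c` the total absolute
#' strength of its nodes, and `m` the total absolute edge weight. A graph
#' with zero total weight scores 0.
#'
#' @param net A [network_model()].
#' @param membership Integer community labels per node (a partition).
#' @return Modularity Q.
#' @export
modularity_q <- function(net, membership) {
  stopifnot(length(membership) == length(net$labels))
  g <- net_to_igraph(net)
  if (igraph::ecount(g) == 0) return(0)
  igraph::modularity(g, membership, weights = igraph::E(g)$weight)
}

rescale_unit <- function(xy) {
  out <- xy
  for (j in seq_len(ncol(xy))) {
    v <- xy[, j]
    rng <- max(v) - min(v)
    out[, j] <- if (rng == 0) rep(0.5, length(v)) else (v - min(v)) / rng
  }
  out
}

#' Fruchterman-Reingold force-directed layout
#'
#' Standard FR particle simulation on the absolute weights (attractive
#' forces proportional to edge magnitude), deterministic given `seed`;
#' final coordinates are rescaled to the unit square (idempotent).
#'
#' @param net A [network_model()].
#' @param seed RNG seed for the initial placement.
#' @param iterations Number of update iterations (default 500).
#' @return A `layout_coordinates`: data frame `coords` (`node`, `x`, `y`
#'   in `[0, 1]`), `seed`, `iterations`.
#' @export
fr_layout <- function(net, seed = 1, iterations = 500) {
  g <- net_to_igraph(net)
  xy <- with_seed(seed, {
    igraph::layout_with_fr(g, niter = iterations,
                           weights = if (igraph::ecount(g) > 0)
                             igraph::E(g)$weight else NULL)
  })
  xy <- rescale_unit(matrix(xy, ncol = 2))
  structure(list(coords = data.frame(node = net$labels,
                                     x = xy[, 1], y = xy[, 2]),
                 seed = seed, iterations = iterations),
            class = "layout_coordinates")
}

#' Average layout across networks
#'
#' A single force-directed coordinate set computed on the element-wise
#' mean of the absolute weight matrices, intended to be reused unchanged
#' for every network in the set so that only edges (and node sizes) differ
#' visually between strata.
#'
#' @param nets List of [network_model()]s over identical node sets.
#' @param seed,iterations Passed to [fr_layout()].
#' @return A `layout_coordinates`.
#' @export
average_layout <- function(nets, seed = 1, iterations = 500) {
  stopifnot(length(nets) >= 1)
  labels <- nets[[1]]$labels
  for (nt in nets) {
    if (!identical(nt$labels, labels)) {
      stop("average_layout() requires identical node sets across networks")
    }
  }
  Wbar <- Reduce(`+`, lapply(nets, function(nt) abs(nt$weights))) /
    length(nets)
  mean_net <- network_model(Wbar, labels = labels,
                            node_types = nets[[1]]$node_types)
  fr_layout(mean_net, seed = seed, iterations = iterations)
}

#' Node sizes as percent change from baseline
#'
#' `size_i = 1 + (mean_Tk_i - mean_T1_i) / mean_T1_i`, floored at
#' `min_size`, so a node drawn at size 1 has an unchanged mean score, and
#' larger/smaller nodes directly show the percent increase/decrease since
#' baseline.
#'
#' @param scores_tk Named per-node means at the time point of interest.
#' @param scores_t1 Named per-node means at baseline (> 0).
#' @param min_size Lower floor for the relative size (default 0.2).
#' @return Named numeric vector of strictly positive relative sizes.
#' @export
node_size_scale <- function(scores_tk, scores_t1, min_size = 0.2) {
  stopifnot(length(scores_tk) == length(scores_t1), min_size > 0)
  bad <- scores_t1 <= 0
  if (any(bad)) {
    stop("baseline mean is zero (or negative) for node '",
         names(scores_t1)[bad][1], "'; relative size is undefined")
  }
  sizes <- 1 + (scores_tk - scores_t1) / scores_t1
  pmax(sizes, min_size)
}
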