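## Centrality of the estimated networks and its bootstrap stability.
##
## Strength is the sum of absolute incident edge weights. Betweenness uses
## Dijkstra shortest paths on the distance transform length = 1 / |weight|
## (stronger association = shorter path), with fractional (Brandes)
## counting over tied geodesics; edges touching the dichotomous node
## participate through their retained magnitude.

net_to_igraph <- function(net, distance = FALSE) {
  W <- abs(net$weights)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  if (distance && igraph::ecount(g) > 0) {
    igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  }
  g
}

#' Node strength
#'
#' @param net A [network_model()].
#' @return Named numeric vector: `strength_i = sum_j |w_ij|`.
#' @export
strength <- function(net) {
  setNames(rowSums(abs(net$weights)), net$labels)
}

#' Weighted betweenness centrality
#'
#' @param net A [network_model()].
#' @param normalized Also return betweenness divided by
#'   `(n - 1)(n - 2) / 2`, the number of node pairs that could route
#'   through a node.
#' @return Data frame: `node`, `degree`, `strength`, `betweenness`,
#'   `betweenness_norm`.
#' @export
betweenness_centrality <- function(net, normalized = TRUE) {
  g <- net_to_igraph(net, distance = TRUE)
  btw <- igraph::betweenness(g, directed = FALSE,
                             weights = if (igraph::ecount(g) > 0)
                               igraph::E(g)$weight else NULL)
  p <- length(net$labels)
  denom <- (p - 1) * (p - 2) / 2
  data.frame(node = net$labels,
             degree = rowSums(net$weights != 0),
             strength = unname(strength(net)),
             betweenness = unname(btw[net$labels]),
             betweenness_norm = if (denom > 0)
               unname(btw[net$labels]) / denom else 0)
}

#' Centrality table for a set of networks
#'
#' @param nets Named list of [network_model()]s.
#' @return Long data frame with `stratum`, `node`, `degree`, `strength`,
#'   `betweenness`, `betweenness_norm`.
#' @export
centrality_table <- function(nets) {
  out <- lapply(names(nets), function(k) {
    cbind(stratum = k, betweenness_centrality(nets[[k]]))
  })
  do.call(rbind, out)
}

#' Bootstrap stability of centrality indices
#'
#' Nonparametric case resampling: `B` replicates draw `n` rows with
#' replacement from the stratum, re-estimate the full network
#' ([estimate_stratum_network()]) and recompute both centrality indices.
#' Replicates whose estimation fails are skipped and counted. The rank
#' stability of a node is the share of replicates in which it keeps its
#' full-sample rank (dense rank, decreasing metric). Deterministic given
#' `seed`.
#'
#' @param stratum A `stratum`.
#' @param config Estimation config passed to [estimate_stratum_network()].
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed RNG seed for the resampling.
#' @return A `bootstrap_summary`: data frame `summary` (per node x metric:
#'   `estimate`, `boot_mean`, `ci_lower`, `ci_upper`, `rank_stability`),
#'   `B`, `B_failed`, `seed`, and `edge_support` (symmetric matrix of
#'   bootstrap edge-inclusion proportions).
#' @export
bootstrap_centrality <- function(stratum, config = list(), B = 1000,
                                 seed = 1) {
  stopifnot(B >= 1)
  full <- estimate_stratum_network(stratum, config)
  base <- betweenness_centrality(full$network)
  p <- length(full$network$labels)
  labels <- full$network$labels
  reps_s <- matrix(NA_real_, B, p, dimnames = list(NULL, labels))
  reps_b <- matrix(NA_real_, B, p, dimnames = list(NULL, labels))
  incl <- matrix(0, p, p, dimnames = list(labels, labels))
  failed <- 0
  row_idx <- with_seed(seed, {
    lapply(seq_len(B), function(b) sample.int(stratum$n, replace = TRUE))
  })
  for (b in seq_len(B)) {
    st_b <- stratum
    st_b$data <- stratum$data[row_idx[[b]], , drop = FALSE]
    est <- try(suppressWarnings(
      estimate_stratum_network(st_b, config)), silent = TRUE)
    if (inherits(est, "try-error")) {
      failed <- failed + 1
      next
    }
    cb <- betweenness_centrality(est$network)
    reps_s[b, ] <- cb$strength
    reps_b[b, ] <- cb$betweenness
    incl <- incl + (est$network$weights != 0)
  }
  ok <- !is.na(reps_s[, 1])
  n_ok <- sum(ok)
  rank_dense <- function(v) match(-v, sort(unique(-v)))
  summarize <- function(reps, point) {
    base_rank <- rank_dense(point)
    rep_ranks <- t(apply(reps[ok, , drop = FALSE], 1, rank_dense))
    data.frame(
      node = labels,
      estimate = point,
      boot_mean = colMeans(reps[ok, , drop = FALSE]),
      ci_lower = apply(reps[ok, , drop = FALSE], 2, quantile, 0.025,
                       names = FALSE),
      ci_upper = apply(reps[ok, , drop = FALSE], 2, quantile, 0.975,
                       names = FALSE),
      rank_stability = colMeans(sweep(rep_ranks, 2, base_rank, "=="))
    )
  }
  if (n_ok == 0) stop("all ", B, " bootstrap replicates failed")
  out <- rbind(cbind(metric = "strength", summarize(reps_s, base$strength)),
               cbind(metric = "betweenness",
                     summarize(reps_b, base$betweenness)))
  rownames(out) <- NULL
  structure(list(summary = out, B = B, B_failed = failed, seed = seed,
                 edge_support = incl / n_ok,
                 network = full$network, fits = full$fits),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat("<bootstrap_summary> B = ", x$B, " (", x$B_failed, " failed), seed = ",
      x$seed, "\n", sep = "")
  print(x$summary)
  invisible(x)
}
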