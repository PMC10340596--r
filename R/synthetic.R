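## Synthetic dyadic cohort generator.
##
## The study data are private, so every downstream stage is exercised on
## cohorts drawn from a conditional-Gaussian model whose stratum-specific
## sparse precision matrices are the planted truth: the off-diagonal
## support of each precision matrix is exactly the conditional-dependence
## graph the mixed-graphical-model stage should recover. Couples and
## repeated measurements are coupled through a Kronecker-structured
## correlation (exchangeable across the two parents, AR(1) across the
## three times) applied to the latent standard-normal factors, the child's
## sex enters designated nodes as a location shift, and the latent scores
## are discretised onto the bounded integer SQ scales.

#' Build a sparse symmetric positive-definite precision matrix
#'
#' Places `-pcor * sqrt(omega_ii * omega_jj)` at each requested off-diagonal
#' position so the implied partial correlation
#' `-omega_ij / sqrt(omega_ii omega_jj)` equals the requested value exactly.
#'
#' @param edges Data frame with columns `i`, `j` (1-based node indices) and
#'   `pcor` (partial correlation, `|pcor| < 1`); may have zero rows.
#' @param n_nodes Number of nodes (default 8, the SQ subscales).
#' @param base_diag Common diagonal value (> 0).
#' @return A symmetric positive-definite `n_nodes x n_nodes` matrix.
#' @export
build_precision <- function(edges, n_nodes = 8, base_diag = 1) {
  stopifnot(base_diag > 0)
  Om <- diag(rep(base_diag, n_nodes))
  if (nrow(edges) > 0) {
    stopifnot(all(abs(edges$pcor) < 1), all(edges$i != edges$j))
    for (r in seq_len(nrow(edges))) {
      i <- edges$i[r]; j <- edges$j[r]
      v <- -edges$pcor[r] * sqrt(Om[i, i] * Om[j, j])
      Om[i, j] <- Om[j, i] <- v
    }
  }
  ev <- min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) {
    stop("requested edge pattern is not positive-definite; ",
         "use smaller partial-correlation magnitudes")
  }
  Om
}

chain_edges <- function(pcor, n_nodes = 8) {
  data.frame(i = seq_len(n_nodes - 1), j = seq_len(n_nodes - 1) + 1,
             pcor = pcor)
}

## Planted conditional-dependence structures for the six strata. These are
## qualitative echoes of the reported result networks (e.g. a maternal
## anxiety hub at baseline, a paternal depression hub at one month, a
## paternal anxiety hub at three months); magnitudes are free parameters of
## the generator, not estimates from the study.
default_planted_edges <- function(pcor = 0.3) {
  idx <- setNames(seq_len(8), sq_subscales())
  e <- function(a, b) c(idx[[a]], idx[[b]])
  build <- function(pairs) {
    m <- do.call(rbind, pairs)
    data.frame(i = m[, 1], j = m[, 2], pcor = pcor)
  }
  list(
    mother_T1 = build(list(e("Anxiety", "Depression"),
                           e("Anxiety", "Somatisation"),
                           e("Anxiety", "Hostility"),
                           e("Anxiety", "Relaxation"),
                           e("PhysicalWellBeing", "Friendliness"))),
    mother_T2 = build(list(e("Somatisation", "Contentedness"),
                           e("Anxiety", "Depression"),
                           e("Relaxation", "PhysicalWellBeing"))),
    mother_T3 = build(list(e("Relaxation", "Anxiety"),
                           e("Relaxation", "Depression"),
                           e("Relaxation", "Contentedness"),
                           e("Depression", "Somatisation"),
                           e("Anxiety", "Hostility"))),
    father_T1 = build(list(e("Relaxation", "Contentedness"),
                           e("Relaxation", "PhysicalWellBeing"),
                           e("Contentedness", "Friendliness"),
                           e("Anxiety", "Hostility"))),
    father_T2 = build(list(e("Depression", "Anxiety"),
                           e("Depression", "Somatisation"),
                           e("Depression", "Hostility"),
                           e("Depression", "Relaxation"))),
    father_T3 = build(list(e("Anxiety", "Depression"),
                           e("Anxiety", "Somatisation"),
                           e("Anxiety", "Hostility"),
                           e("Anxiety", "Relaxation")))
  )
}

#' Generative specification for a synthetic dyadic cohort
#'
#' Defaults reproduce the study's design: 23 enrolled mother-father dyads,
#' the fathers of the last 7 dyads missing at T2/T3 (so complete-case
#' filtering retains 16 pairs), three time points, bounded integer SQ
#' scores, and a different planted sparse conditional-dependence graph per
#' role x time stratum.
#'
#' @param n_dyads Number of enrolled dyads.
#' @param precision Named list of 6 SPD precision matrices
#'   (`mother_T1`, .., `father_T3`) over the 8 continuous nodes.
#' @param sex_effect Named numeric vector (subscale -> shift, in latent SD
#'   units) applied as `+effect/2` for a male child and `-effect/2` for a
#'   female child.
#' @param dyad_rho Within-couple latent correlation in `[0, 1)`.
#' @param time_rho Lag-1 latent autocorrelation in `[0, 1)`.
#' @param dropout Integer indices of dyads whose father records are removed
#'   at T2 and T3 (never at T1).
#' @param scale_ranges Per-subscale maxima for discretisation.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_dyads = 23,
                           precision = lapply(default_planted_edges(),
                                              build_precision),
                           sex_effect = c(Somatisation = 0.5,
                                          Contentedness = 0.5),
                           dyad_rho = 0.3,
                           time_rho = 0.4,
                           dropout = seq_len(7) + 16L,
                           scale_ranges = default_scale_ranges(),
                           seed = 101L) {
  stopifnot(n_dyads >= 1,
            dyad_rho >= 0, dyad_rho < 1,
            time_rho >= 0, time_rho < 1,
            length(dropout) <= n_dyads)
  stratum_keys <- paste(rep(parent_roles(), each = 3), time_points(),
                        sep = "_")
  stopifnot(setequal(names(precision), stratum_keys))
  for (k in stratum_keys) {
    ev <- min(eigen(precision[[k]], symmetric = TRUE,
                    only.values = TRUE)$values)
    if (ev <= 0) stop("precision matrix '", k, "' is not positive-definite")
  }
  eff <- setNames(numeric(8), sq_subscales())
  eff[names(sex_effect)] <- sex_effect
  structure(list(n_dyads = as.integer(n_dyads),
                 precision = precision[stratum_keys],
                 sex_effect = eff,
                 dyad_rho = dyad_rho, time_rho = time_rho,
                 dropout = as.integer(dropout),
                 scale_ranges = scale_ranges,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Discretise latent scores onto bounded integer scales
#'
#' Each column is affinely mapped from its observed range onto
#' `[0, scale_max]`, rounded, and clamped; the map is monotone in the
#' latent value. A constant column maps to the scale midpoint.
#'
#' @param latent Numeric matrix whose column names are subscales.
#' @param scale_ranges Named per-subscale maxima.
#' @return Integer matrix of the same shape.
#' @export
discretize_scores <- function(latent, scale_ranges = default_scale_ranges()) {
  stopifnot(all(is.finite(latent)), !is.null(colnames(latent)))
  out <- latent
  for (s in colnames(latent)) {
    smax <- scale_ranges[[s]]
    v <- latent[, s]
    rng <- max(v) - min(v)
    out[, s] <- if (rng == 0) round(smax / 2) else
      pmin(pmax(round((v - min(v)) / rng * smax), 0), smax)
  }
  storage.mode(out) <- "integer"
  out
}

## Correlation of the 6 latent cells per dyad, ordered
## (mother,T1..T3, father,T1..T3): exchangeable across roles, AR(1) across
## times, combined as a Kronecker product.
cell_correlation <- function(dyad_rho, time_rho) {
  C_role <- matrix(c(1, dyad_rho, dyad_rho, 1), 2)
  C_time <- time_rho^abs(outer(1:3, 1:3, "-"))
  kronecker(C_role, C_time)
}

#' Generate a synthetic cohort and its planted truth
#'
#' For every dyad, 6 latent 8-vectors (role x time cells) are drawn so that
#' each cell is marginally `N(0, solve(precision[cell]))` while sharing
#' standard-normal factors whose cross-cell correlation is exchangeable
#' across roles and AR(1) across times (a Kronecker product of the two);
#' the child's sex (Bernoulli 1/2, constant per dyad)
#' shifts the designated nodes; all latent scores are then discretised and
#' the dropout pattern removes father records at T2/T3.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `cohort` (a [cohort_table()]), `truth` (list:
#'   `adjacency_by_stratum`, signed 0/+1/-1 matrices over the 9 network
#'   nodes; `community_partition`, connected-component labels per
#'   stratum), and `latent` (the pre-discretisation score matrices per
#'   stratum, useful for fidelity diagnostics).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_dyads
    keys <- names(spec$precision)
    chol_sigma <- lapply(spec$precision, function(Om) chol(solve(Om)))
    Cc <- cell_correlation(spec$dyad_rho, spec$time_rho)
    Lc <- t(chol(Cc))
    sex <- rbinom(n, 1, 0.5)
    latent <- vector("list", length(keys))
    names(latent) <- keys
    for (k in keys) latent[[k]] <- matrix(NA_real_, n, 8,
                                          dimnames = list(NULL, sq_subscales()))
    for (d in seq_len(n)) {
      Z <- matrix(rnorm(6 * 8), 6, 8)
      U <- Lc %*% Z                       # rows: cells, correlated by Cc
      for (ci in seq_along(keys)) {
        k <- keys[ci]
        x <- drop(t(chol_sigma[[k]]) %*% U[ci, ])
        x <- x + spec$sex_effect * (sex[d] - 0.5)
        latent[[k]][d, ] <- x
      }
    }
    all_latent <- do.call(rbind, latent)
    scores <- discretize_scores(all_latent, spec$scale_ranges)
    rows <- list()
    ids <- sprintf("D%02d", seq_len(n))
    for (ci in seq_along(keys)) {
      k <- keys[ci]
      role <- sub("_T[123]$", "", k)
      tp <- sub("^[a-z]+_", "", k)
      block <- scores[(ci - 1) * n + seq_len(n), , drop = FALSE]
      rows[[k]] <- data.frame(dyad_id = ids, parent_role = role,
                              time_point = tp, block,
                              child_sex = child_sexes()[sex + 1],
                              check.names = FALSE)
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    drop_rows <- df$parent_role == "father" & df$time_point != "T1" &
      df$dyad_id %in% ids[spec$dropout]
    df <- df[!drop_rows, , drop = FALSE]
    rownames(df) <- NULL
    list(cohort = cohort_table(df, spec$scale_ranges),
         truth = planted_truth(spec),
         ## pre-discretisation scores, kept for fidelity diagnostics:
         ## round-and-clamp attenuates associations slightly on the
         ## coarser well-being scales
         latent = latent)
  })
}

planted_truth <- function(spec) {
  adjacency <- lapply(spec$precision, function(Om) {
    A9 <- matrix(0L, 9, 9,
                 dimnames = list(network_node_labels(),
                                 network_node_labels()))
    S <- -sign(Om)
    diag(S) <- 0
    A9[1:8, 1:8] <- S
    A9
  })
  partition <- lapply(adjacency, function(A) {
    g <- igraph::graph_from_adjacency_matrix(abs(A), mode = "undirected")
    setNames(as.integer(igraph::components(g)$membership),
             network_node_labels())
  })
  list(adjacency_by_stratum = adjacency, community_partition = partition)
}
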