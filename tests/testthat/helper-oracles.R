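# Independent oracles and small fixture builders shared across the suite.

# Exhaustive-path betweenness: enumerate every simple path between every
# node pair, keep the shortest under length = 1/|w|, and count fractional
# pass-through per intermediate node. Only usable on small graphs.
brute_betweenness <- function(W, tol = 1e-9) {
  W <- abs(W)
  n <- nrow(W)
  btw <- numeric(n)
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(path, len) {
      v <- path[length(path)]
      if (v == t) {
        paths[[length(paths) + 1]] <<- list(path = path, len = len)
        return(invisible(NULL))
      }
      for (u in which(W[v, ] > 0)) {
        if (!(u %in% path)) walk(c(path, u), len + 1 / W[v, u])
      }
    }
    walk(s, 0)
    paths
  }
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      ps <- all_paths(s, t)
      if (length(ps) == 0) next
      lens <- vapply(ps, `[[`, 0, "len")
      shortest <- ps[lens <= min(lens) * (1 + tol)]
      sigma <- length(shortest)
      for (p in shortest) {
        inner <- setdiff(p$path, c(s, t))
        btw[inner] <- btw[inner] + 1 / sigma
      }
    }
  }
  btw
}

# Repeated-measures sums of squares computed cell by cell, nothing shared
# with the implementation.
brute_rm_F <- function(M) {
  n <- nrow(M); t <- ncol(M)
  g <- mean(M)
  ss_time <- 0
  for (j in 1:t) ss_time <- ss_time + n * (mean(M[, j]) - g)^2
  ss_subj <- 0
  for (i in 1:n) ss_subj <- ss_subj + t * (mean(M[i, ]) - g)^2
  ss_tot <- 0
  for (i in 1:n) for (j in 1:t) ss_tot <- ss_tot + (M[i, j] - g)^2
  ss_err <- ss_tot - ss_time - ss_subj
  ((ss_time / (t - 1))) / (ss_err / ((t - 1) * (n - 1)))
}

# Random small weighted network for oracle comparisons.
random_small_net <- function(n_nodes, p_edge = 0.5, signed = TRUE) {
  W <- matrix(0, n_nodes, n_nodes)
  for (i in 1:(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (runif(1) < p_edge) {
        w <- runif(1, 0.1, 1) * if (signed && runif(1) < 0.3) -1 else 1
        W[i, j] <- W[j, i] <- w
      }
    }
  }
  labs <- paste0("n", seq_len(n_nodes))
  dimnames(W) <- list(labs, labs)
  network_model(W, labels = labs, node_types = rep("continuous", n_nodes))
}

# Complete two-role three-time cohort with scores filled deterministically.
make_complete_cohort <- function(n_dyads, seed = 42) {
  set.seed(seed)
  grid <- expand.grid(dyad_id = sprintf("D%02d", seq_len(n_dyads)),
                      parent_role = c("mother", "father"),
                      time_point = c("T1", "T2", "T3"),
                      stringsAsFactors = FALSE)
  ranges <- default_scale_ranges()
  for (s in sq_subscales()) {
    grid[[s]] <- sample(0:ranges[[s]], nrow(grid), replace = TRUE)
  }
  sex <- sample(c("female", "male"), n_dyads, replace = TRUE)
  grid$child_sex <- sex[match(grid$dyad_id,
                              sprintf("D%02d", seq_len(n_dyads)))]
  cohort_table(grid)
}

# Fabricated nodewise fits for aggregation tests: `coef_mat[i, j]` is the
# coefficient of node j in node i's regression.
fits_from_matrix <- function(coef_mat, node_types = NULL) {
  labs <- rownames(coef_mat)
  if (is.null(node_types)) node_types <- rep("continuous", nrow(coef_mat))
  fits <- lapply(seq_along(labs), function(i) {
    structure(list(node = labs[i], node_type = node_types[i],
                   lambda_selected = 0.1, lambda_grid = 0.1,
                   cv_mean = 0, cv_se = 0,
                   coefficients = coef_mat[i, -i],
                   isolated = FALSE),
              class = "nodewise_fit")
  })
  names(fits) <- labs
  fits
}

# Synthetic spec with the same precision matrix planted in all six strata.
uniform_spec <- function(prec, n_dyads, seed, sex_effect = c(Anxiety = 0),
                         dyad_rho = 0, time_rho = 0) {
  keys <- paste(rep(c("mother", "father"), each = 3),
                c("T1", "T2", "T3"), sep = "_")
  synthetic_spec(n_dyads = n_dyads,
                 precision = setNames(rep(list(prec), 6), keys),
                 sex_effect = sex_effect,
                 dyad_rho = dyad_rho, time_rho = time_rho,
                 dropout = integer(0), seed = seed)
}
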