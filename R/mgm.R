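## Mixed graphical model estimation by nodewise L1-regularised regression.
##
## Each node is regressed on all others (Gaussian least squares for the 8
## continuous subscales, logistic for the dichotomous child-sex node) with
## a lasso penalty; the penalty weight is tuned by seeded K-fold
## cross-validation on a fixed log-spaced grid and edges are aggregated
## across the two directed fits with the conservative AND rule. Absence of
## an edge encodes conditional independence of the two variables given all
## the others (pairwise interactions only).

#' Cross-validated lasso fit for one node
#'
#' The grid holds `n_lambda` log-spaced values from `lambda_max` (the
#' smallest penalty that zeroes every coefficient) down to
#' `lambda_min_ratio * lambda_max`. Folds are a seeded random partition of
#' the rows into `folds` parts; held-out loss is squared error for
#' continuous nodes and binomial deviance for the categorical node. The
#' returned penalty is chosen by the one-standard-error rule by default
#' (the sparsest model within one SE of the minimum mean loss), keeping
#' false-positive selections rare; `select = "min"` takes the loss minimum
#' instead.
#'
#' @param y Response vector (continuous, or 0/1 for categorical).
#' @param x Predictor matrix (expected standardized; see
#'   [estimate_stratum_network()]).
#' @param node_type `"continuous"` or `"categorical"`.
#' @param folds Number of CV folds (default 10); requires `n >= folds`.
#' @param n_lambda,lambda_min_ratio Grid shape.
#' @param lambda_grid Optional explicit grid overriding the constructed
#'   one (may include 0 for the unpenalized limit).
#' @param select `"1se"` (default) or `"min"`.
#' @param seed Seed for the fold partition.
#' @return A `nodewise_fit`: `node`, `node_type`, `lambda_selected`,
#'   `lambda_grid`, `cv_mean`, `cv_se`, `coefficients` (named, excludes the
#'   node itself), `isolated` flag.
#' @export
cross_validate_lambda <- function(y, x, node_type = c("continuous",
                                                      "categorical"),
                                  folds = 10, n_lambda = 50,
                                  lambda_min_ratio = 1e-3,
                                  lambda_grid = NULL,
                                  select = c("1se", "min"),
                                  seed = 1) {
  node_type <- match.arg(node_type)
  select <- match.arg(select)
  x <- as.matrix(x)
  n <- length(y)
  if (n < folds) {
    stop("n (", n, ") is smaller than the number of folds (", folds,
         "); use fewer folds")
  }
  cnames <- colnames(x)
  if (is.null(cnames)) cnames <- paste0("V", seq_len(ncol(x)))
  zero_fit <- function() {
    structure(list(node = NA_character_, node_type = node_type,
                   lambda_selected = NA_real_, lambda_grid = numeric(0),
                   cv_mean = numeric(0), cv_se = numeric(0),
                   coefficients = setNames(rep(0, ncol(x)), cnames),
                   isolated = TRUE),
              class = "nodewise_fit")
  }
  if (node_type == "categorical" && length(unique(y)) < 2) {
    warning("categorical response is constant; node left isolated")
    return(zero_fit())
  }
  if (node_type == "continuous" && stats::var(y) == 0) {
    warning("continuous response is constant; node left isolated")
    return(zero_fit())
  }
  family <- if (node_type == "continuous") "gaussian" else "binomial"
  if (is.null(lambda_grid)) {
    lambda_max <- max(abs(crossprod(x, y - mean(y)))) / n
    lambda_grid <- exp(seq(log(lambda_max),
                           log(lambda_max * lambda_min_ratio),
                           length.out = n_lambda))
  }
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  nlam <- length(lambda_grid)
  loss <- matrix(NA_real_, folds, nlam)
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    if (family == "binomial" && length(unique(y[tr])) < 2) next
    fit <- suppressWarnings(
      glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = family,
                     lambda = lambda_grid, standardize = FALSE))
    ## linear predictor at every grid value, without predict() overhead;
    ## glmnet fits all user-supplied lambdas so the path is complete
    eta <- x[!tr, , drop = FALSE] %*% as.matrix(fit$beta)
    eta <- sweep(eta, 2, fit$a0, "+")
    nfit <- ncol(eta)
    if (family == "gaussian") {
      loss[k, seq_len(nfit)] <- colMeans((eta - y[!tr])^2)
    } else {
      p <- pmin(pmax(stats::plogis(eta), 1e-10), 1 - 1e-10)
      loss[k, seq_len(nfit)] <- colMeans(-2 * (y[!tr] * log(p) +
                                                 (1 - y[!tr]) * log(1 - p)))
    }
    if (nfit < nlam) loss[k, (nfit + 1):nlam] <- loss[k, nfit]
  }
  used <- !apply(is.na(loss), 1, all)
  if (!any(used)) {
    warning("no usable CV fold; node left isolated")
    return(zero_fit())
  }
  cv_mean <- colMeans(loss[used, , drop = FALSE])
  cv_se <- apply(loss[used, , drop = FALSE], 2, stats::sd) / sqrt(sum(used))
  i_min <- which.min(cv_mean)
  i_sel <- if (select == "min") i_min else
    min(which(cv_mean <= cv_mean[i_min] + cv_se[i_min]))
  full <- suppressWarnings(
    glmnet::glmnet(x, y, family = family, lambda = lambda_grid,
                   standardize = FALSE,
                   thresh = if (any(lambda_grid == 0)) 1e-12 else 1e-7))
  bmat <- as.matrix(full$beta)
  beta <- if (i_sel <= ncol(bmat)) bmat[, i_sel] else bmat[, ncol(bmat)]
  beta <- as.numeric(beta)
  structure(list(node = NA_character_, node_type = node_type,
                 lambda_selected = lambda_grid[i_sel],
                 lambda_grid = lambda_grid,
                 cv_mean = cv_mean, cv_se = cv_se,
                 coefficients = setNames(beta, cnames),
                 isolated = FALSE),
            class = "nodewise_fit")
}

#' Aggregate nodewise fits into an undirected network
#'
#' With the AND rule (default), edge (i, j) exists only when the j
#' coefficient in node i's fit and the i coefficient in node j's fit are
#' both nonzero; the OR rule requires either. The edge weight is the mean
#' of the two absolute standardized coefficients. Continuous-continuous
#' edges take the shared coefficient sign; pairs whose two fits disagree in
#' sign are dropped and listed in `unstable`. Edges involving the
#' dichotomous node are unsigned (magnitude retained for path
#' computations).
#'
#' @param fits Named list of `nodewise_fit` objects, one per node, whose
#'   names are the node labels.
#' @param rule `"and"` (default) or `"or"`.
#' @param parent_role,time_point,n Metadata forwarded to the network.
#' @return A [network_model()].
#' @export
aggregate_and_rule <- function(fits, rule = c("and", "or"),
                               parent_role = NA_character_,
                               time_point = NA_character_,
                               n = NA_integer_) {
  rule <- match.arg(rule)
  labels <- names(fits)
  stopifnot(!is.null(labels), length(labels) == length(fits))
  p <- length(labels)
  node_types <- vapply(fits, function(f) f$node_type, character(1))
  B <- matrix(0, p, p, dimnames = list(labels, labels))
  for (i in seq_len(p)) {
    B[i, names(fits[[i]]$coefficients)] <- fits[[i]]$coefficients
  }
  W <- matrix(0, p, p, dimnames = list(labels, labels))
  unstable <- list()
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      bij <- B[i, j]; bji <- B[j, i]
      present <- if (rule == "and") bij != 0 && bji != 0 else
        bij != 0 || bji != 0
      if (!present) next
      both_cont <- node_types[i] == "continuous" &&
        node_types[j] == "continuous"
      w <- if (rule == "and") (abs(bij) + abs(bji)) / 2 else
        mean(abs(c(bij, bji)[c(bij, bji) != 0]))
      if (both_cont) {
        s_ij <- sign(bij); s_ji <- sign(bji)
        if (rule == "and" && s_ij != s_ji) {
          unstable[[length(unstable) + 1]] <-
            data.frame(node_i = labels[i], node_j = labels[j])
          next
        }
        sgn <- if (s_ij != 0) s_ij else s_ji
        W[i, j] <- W[j, i] <- sgn * w
      } else {
        W[i, j] <- W[j, i] <- w
      }
    }
  }
  unstable <- if (length(unstable)) do.call(rbind, unstable) else NULL
  network_model(W, labels = labels, node_types = node_types,
                parent_role = parent_role, time_point = time_point,
                n = n, unstable = unstable)
}

#' Estimate the mixed graphical model of one stratum
#'
#' Standardizes all 9 columns (z-score per stratum; the dichotomous node is
#' kept 0/1 as a response but standardized as a predictor), runs
#' [cross_validate_lambda()] per node (Gaussian for the 8 subscales,
#' logistic for child sex), and aggregates with [aggregate_and_rule()].
#' Deterministic given `seed`. A constant column leaves its node isolated
#' with a warning.
#'
#' @param stratum A `stratum` from [stratify()], or any list with a numeric
#'   `data` matrix (8 continuous columns + final 0/1 column) plus `n`.
#' @param config List of options: `folds` (10), `n_lambda` (50),
#'   `lambda_min_ratio` (1e-3), `select` ("1se" or "min"), `rule` ("and" or
#'   "or"), `min_n` (10), `seed` (1).
#' @return List with `network` (a [network_model()]) and `fits` (the 9
#'   `nodewise_fit`s).
#' @export
estimate_stratum_network <- function(stratum, config = list()) {
  cfg <- modifyList(list(folds = 10, n_lambda = 50, lambda_min_ratio = 1e-3,
                         select = "1se", rule = "and", min_n = 10, seed = 1),
                    config)
  D <- stratum$data
  n <- nrow(D)
  if (n < cfg$min_n) {
    stop("stratum has n = ", n, " below the minimum of ", cfg$min_n)
  }
  p <- ncol(D)
  labels <- colnames(D)
  node_types <- c(rep("continuous", p - 1), "categorical")
  ## standardized predictor matrix; constant columns flagged
  sds <- apply(D, 2, stats::sd)
  Z <- D
  for (j in seq_len(p)) {
    Z[, j] <- if (sds[j] > 0) (D[, j] - mean(D[, j])) / sds[j] else 0
  }
  fits <- vector("list", p)
  names(fits) <- labels
  for (j in seq_len(p)) {
    y <- if (node_types[j] == "continuous") Z[, j] else D[, j]
    x <- Z[, -j, drop = FALSE]
    if (sds[j] == 0) {
      warning("column '", labels[j], "' is constant; node left isolated")
      fits[[j]] <- suppressWarnings(
        cross_validate_lambda(rep(0, n), x, node_types[j],
                              folds = cfg$folds, seed = cfg$seed + j))
      fits[[j]]$isolated <- TRUE
      fits[[j]]$coefficients[] <- 0
    } else {
      fits[[j]] <- cross_validate_lambda(
        y, x, node_types[j], folds = cfg$folds, n_lambda = cfg$n_lambda,
        lambda_min_ratio = cfg$lambda_min_ratio, select = cfg$select,
        seed = cfg$seed + j)
    }
    fits[[j]]$node <- labels[j]
  }
  net <- aggregate_and_rule(fits, rule = cfg$rule,
                            parent_role = stratum$parent_role,
                            time_point = stratum$time_point, n = n)
  list(network = net, fits = fits)
}

#' Node predictability
#'
#' How well each node is predicted by its network neighbours: for
#' continuous nodes the in-sample R2 of an unpenalized refit on the
#' selected neighbours (0 for isolated nodes, clamped to `[0, 1]`); for the
#' categorical node the correct-classification rate CC of a logistic refit,
#' the marginal (majority-class) accuracy CCmarg, and the normalized
#' accuracy `nCC = (CC - CCmarg) / (1 - CCmarg)` (clamped at 0, and 0 when
#' `CCmarg = 1`).
#'
#' @param fits Nodewise fits from [estimate_stratum_network()].
#' @param stratum The stratum the fits were estimated on.
#' @param net Optional [network_model()]; defaults to the AND-rule
#'   aggregation of `fits`.
#' @return Data frame: `node`, `node_type`, `R2`, `CC`, `CCmarg`, `nCC`
#'   (NA where not applicable).
#' @export
predictability <- function(fits, stratum, net = NULL) {
  if (is.null(net)) net <- aggregate_and_rule(fits)
  D <- stratum$data
  labels <- names(fits)
  out <- data.frame(node = labels,
                    node_type = vapply(fits, function(f) f$node_type,
                                       character(1)),
                    R2 = NA_real_, CC = NA_real_, CCmarg = NA_real_,
                    nCC = NA_real_)
  for (j in seq_along(labels)) {
    nbrs <- labels[net$weights[labels[j], ] != 0]
    if (out$node_type[j] == "continuous") {
      y <- D[, labels[j]]
      if (length(nbrs) == 0 || stats::var(y) == 0) {
        out$R2[j] <- 0
        next
      }
      fit <- lm(y ~ ., data = as.data.frame(D[, nbrs, drop = FALSE]))
      r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
      out$R2[j] <- min(max(r2, 0), 1)
    } else {
      y <- D[, labels[j]]
      ccmarg <- max(mean(y), 1 - mean(y))
      out$CCmarg[j] <- ccmarg
      if (length(nbrs) == 0 || length(unique(y)) < 2) {
        out$CC[j] <- ccmarg
        out$nCC[j] <- 0
        next
      }
      df <- as.data.frame(D[, nbrs, drop = FALSE])
      fit <- suppressWarnings(glm(y ~ ., family = stats::binomial(),
                                  data = df))
      pred <- as.integer(predict(fit, type = "response") >= 0.5)
      cc <- mean(pred == y)
      out$CC[j] <- cc
      out$nCC[j] <- if (ccmarg < 1) {
        max((cc - ccmarg) / (1 - ccmarg), 0)
      } else 0
    }
  }
  out
}

#' @importFrom stats residuals
NULL
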