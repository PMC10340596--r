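test_that("the unpenalized limit reproduces least squares", {
  set.seed(12)
  n <- 60
  X <- qr.Q(qr(matrix(rnorm(n * 5), n)))[, 1:5] * sqrt(n)  # orthonormal-ish
  beta <- c(1, -0.5, 0.3, 0, 0.8)
  y <- drop(X %*% beta) + rnorm(n, sd = 0.1)
  fit <- cross_validate_lambda(y, X, "continuous", lambda_grid = 0, seed = 1)
  ols <- coef(lm(y ~ X))[-1]
  expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-6)
})

test_that("cross-validated selection is sparse under the null and finds signal", {
  set.seed(20)
  # null: y independent of X
  n_nonzero <- replicate(50, {
    X <- scale(matrix(rnorm(200 * 8), 200))
    y <- as.numeric(scale(rnorm(200)))
    fit <- cross_validate_lambda(y, X, "continuous",
                                 seed = sample.int(1e6, 1))
    sum(fit$coefficients != 0)
  })
  expect_gte(mean(n_nonzero <= 1), 0.9)

  # signal on x1 only
  hits <- replicate(50, {
    X <- scale(matrix(rnorm(500 * 8), 500))
    y <- as.numeric(scale(0.8 * X[, 1] + rnorm(500)))
    fit <- cross_validate_lambda(y, X, "continuous",
                                 seed = sample.int(1e6, 1))
    fit$coefficients[1] != 0 && all(fit$coefficients[-1] == 0)
  })
  expect_gte(mean(hits), 0.9)

  # selected lambda always comes from the searched grid
  X <- scale(matrix(rnorm(100 * 8), 100))
  y <- as.numeric(scale(rnorm(100)))
  fit <- cross_validate_lambda(y, X, "continuous", seed = 3)
  expect_true(fit$lambda_selected %in% fit$lambda_grid)

  # too few rows for the folds
  expect_error(cross_validate_lambda(rnorm(5), matrix(rnorm(40), 5),
                                     "continuous", folds = 10), "folds")
})

test_that("AND-rule aggregation, sign handling and rule nesting", {
  labs <- c("A", "B", "C")
  cm <- matrix(0, 3, 3, dimnames = list(labs, labs))
  # one-sided selection: no edge under AND
  cm["A", "B"] <- 0.4
  netA <- aggregate_and_rule(fits_from_matrix(cm))
  expect_equal(sum(netA$weights != 0), 0)
  # both sides: mean of absolute weights, shared positive sign
  cm["B", "A"] <- 0.2
  netB <- aggregate_and_rule(fits_from_matrix(cm))
  expect_equal(netB$weights["A", "B"], 0.3)
  # sign conflict: edge excluded and logged
  cm["B", "A"] <- -0.4
  netC <- aggregate_and_rule(fits_from_matrix(cm))
  expect_equal(sum(netC$weights != 0), 0)
  expect_equal(nrow(netC$unstable), 1)
  # mixed edges are unsigned magnitudes
  cm2 <- matrix(0, 3, 3, dimnames = list(labs, labs))
  cm2["A", "C"] <- -0.4; cm2["C", "A"] <- 0.2
  netD <- aggregate_and_rule(fits_from_matrix(
    cm2, node_types = c("continuous", "continuous", "categorical")))
  expect_equal(netD$weights["A", "C"], 0.3)

  # AND edge set is a subset of OR on the same fits
  set.seed(8)
  cm3 <- matrix(rnorm(25) * rbinom(25, 1, 0.4), 5, 5,
                dimnames = list(letters[1:5], letters[1:5]))
  diag(cm3) <- 0
  fits3 <- fits_from_matrix(cm3)
  and_edges <- aggregate_and_rule(fits3, rule = "and")$weights != 0
  or_edges <- aggregate_and_rule(fits3, rule = "or")$weights != 0
  expect_true(all(or_edges[and_edges]))

  # symmetry is exact
  expect_identical(netB$weights, t(netB$weights))
})

test_that("stratum estimation is deterministic and guards its inputs", {
  prec <- build_precision(data.frame(i = 1:7, j = 2:8, pcor = 0.3))
  st <- stratify(generate_cohort(uniform_spec(prec, 40, seed = 2))$cohort)$mother_T1
  e1 <- estimate_stratum_network(st, list(seed = 7))
  e2 <- estimate_stratum_network(st, list(seed = 7))
  expect_identical(e1$network$weights, e2$network$weights)

  # n below the configured minimum
  small <- st; small$data <- st$data[1:5, ]; small$n <- 5
  expect_error(estimate_stratum_network(small, list(min_n = 10, folds = 3)),
               "minimum")

  # a constant column isolates its node with a warning
  stc <- st
  stc$data[, "Friendliness"] <- 3
  expect_warning(ec <- estimate_stratum_network(stc, list(seed = 7)),
                 "constant")
  expect_true(all(ec$network$weights["Friendliness", ] == 0))
})

test_that("predictability decomposes explained variance and accuracy", {
  prec <- build_precision(data.frame(i = 1, j = 2, pcor = 0.4))
  st <- stratify(generate_cohort(uniform_spec(prec, 60, seed = 4))$cohort)$mother_T1
  est <- estimate_stratum_network(st, list(seed = 1))
  pr <- predictability(est$fits, st, est$network)
  expect_true(all(pr$R2[pr$node_type == "continuous"] >= 0 &
                    pr$R2[pr$node_type == "continuous"] <= 1))
  # isolated continuous nodes score exactly 0
  deg <- rowSums(est$network$weights != 0)
  iso <- pr$node[pr$node_type == "continuous" & deg[pr$node] == 0]
  expect_true(all(pr$R2[pr$node %in% iso] == 0))
  # categorical node with no neighbours: CC = CCmarg, nCC = 0
  sexrow <- pr[pr$node == "child_sex", ]
  if (sum(est$network$weights["child_sex", ] != 0) == 0) {
    expect_equal(sexrow$CC, sexrow$CCmarg)
    expect_equal(sexrow$nCC, 0)
  }
  # the nCC formula itself
  expect_equal((0.9 - 0.8) / (1 - 0.8), 0.5)

  # exact linear dependence gives R2 = 1
  st2 <- st
  st2$data[, "Anxiety"] <- 2 * st2$data[, "Depression"] -
    st2$data[, "Hostility"]
  fits2 <- est$fits
  W <- matrix(0, 9, 9, dimnames = list(network_node_labels(),
                                       network_node_labels()))
  W["Anxiety", c("Depression", "Hostility")] <- 0.5
  W[c("Depression", "Hostility"), "Anxiety"] <- 0.5
  net2 <- network_model(W)
  pr2 <- predictability(fits2, st2, net2)
  expect_equal(pr2$R2[pr2$node == "Anxiety"], 1, tolerance = 1e-9)

  # refit R2 never decreases when a truly predictive neighbour is added
  W1 <- matrix(0, 9, 9, dimnames = dimnames(W))
  W1["Anxiety", "Depression"] <- W1["Depression", "Anxiety"] <- 0.5
  pr_small <- predictability(fits2, st2, network_model(W1))
  expect_lte(pr_small$R2[pr_small$node == "Anxiety"],
             pr2$R2[pr2$node == "Anxiety"] + 1e-12)
})
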