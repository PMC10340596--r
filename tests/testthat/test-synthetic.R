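test_that("build_precision places the requested partial correlations", {
  # no edges: diagonal, all implied partials zero
  Om0 <- build_precision(data.frame(i = integer(0), j = integer(0),
                                    pcor = numeric(0)))
  expect_equal(Om0, diag(8))

  # single edge: implied partial equals the request exactly
  Om1 <- build_precision(data.frame(i = 1, j = 2, pcor = 0.3))
  expect_equal(-Om1[1, 2] / sqrt(Om1[1, 1] * Om1[2, 2]), 0.3)

  # chain of 4 at 0.25: SPD, and the partials recovered by full matrix
  # inversion of the implied covariance agree with the request
  Om <- build_precision(data.frame(i = 1:3, j = 2:4, pcor = 0.25),
                        n_nodes = 4)
  expect_true(min(eigen(Om, symmetric = TRUE)$values) > 0)
  Sigma <- solve(Om)                      # implied covariance
  P <- -stats::cov2cor(solve(Sigma))      # partials via inversion oracle
  expect_equal(P[1, 2], 0.25, tolerance = 1e-9)
  expect_equal(P[2, 3], 0.25, tolerance = 1e-9)
  expect_equal(P[1, 3], 0, tolerance = 1e-9)

  # an impossible pattern is refused with advice
  dense <- expand.grid(i = 1:8, j = 1:8)
  dense <- dense[dense$i < dense$j, ]
  dense$pcor <- 0.9
  expect_error(build_precision(dense), "smaller")
})

test_that("generation is deterministic and honors the dropout pattern", {
  spec <- synthetic_spec()
  g1 <- generate_cohort(spec)
  g2 <- generate_cohort(spec)
  expect_identical(g1$cohort, g2$cohort)

  # default study design: 23 enrolled, 16 complete after filtering
  cc <- complete_case_filter(g1$cohort)
  expect_equal(cc$report$n_enrolled, 23)
  expect_equal(cc$report$n_complete, 16)

  # dropout removes father records at T2/T3 only, never T1
  dropped <- sprintf("D%02d", spec$dropout)
  miss <- g1$cohort[g1$cohort$dyad_id %in% dropped, ]
  expect_true(all(table(miss$parent_role, miss$time_point)["father", ] ==
                    c(T1 = 7, T2 = 0, T3 = 0)))
  expect_true(all(table(miss$parent_role, miss$time_point)["mother", ] == 7))

  # scores respect their configured bounds
  for (s in sq_subscales()) {
    expect_true(all(g1$cohort[[s]] >= 0 &
                      g1$cohort[[s]] <= default_scale_ranges()[[s]]))
  }

  # planted truth mirrors the precision support
  truth <- g1$truth
  expect_equal(sum(truth$adjacency_by_stratum$mother_T1[1:8, 1:8] != 0) / 2, 5)
  expect_true(all(diag(truth$adjacency_by_stratum$father_T3) == 0))
})

test_that("discretization is a monotone map onto the score range", {
  set.seed(7)
  latent <- matrix(rnorm(600), ncol = 2,
                   dimnames = list(NULL, c("Anxiety", "Relaxation")))
  sc <- discretize_scores(latent)
  expect_true(all(sc[, "Anxiety"] %in% 0:17))
  expect_true(all(sc[, "Relaxation"] %in% 0:6))
  # extremes hit the scale endpoints
  expect_equal(unname(sc[which.min(latent[, 1]), 1]), 0L)
  expect_equal(unname(sc[which.max(latent[, 1]), 1]), 17L)
  # monotone: sorting by latent value sorts the scores (sort oracle)
  ord <- order(latent[, 1])
  expect_true(all(diff(sc[ord, 1]) >= 0))
  # constant column maps to the (rounded) midpoint of the 0..17 range
  const <- matrix(1, 5, 1, dimnames = list(NULL, "Anxiety"))
  expect_true(all(discretize_scores(const) == round(17 / 2)))
})

test_that("uncoupled strata are empirically independent at large n", {
  prec <- build_precision(data.frame(i = 1:7, j = 2:8, pcor = 0.3))
  spec <- uniform_spec(prec, n_dyads = 5000, seed = 11)
  co <- generate_cohort(spec)$cohort
  strata <- stratify(co)
  a_m1 <- strata$mother_T1$data[, "Anxiety"]
  a_f1 <- strata$father_T1$data[, "Anxiety"]
  a_m2 <- strata$mother_T2$data[, "Anxiety"]
  expect_lt(abs(cor(a_m1, a_f1)), 0.05)  # cross-role
  expect_lt(abs(cor(a_m1, a_m2)), 0.05)  # cross-time
})

test_that("sample partial correlations converge to the planted values", {
  prec <- build_precision(data.frame(i = 1:7, j = 2:8, pcor = 0.3))
  spec <- uniform_spec(prec, n_dyads = 5000, seed = 23)
  gen <- generate_cohort(spec)
  P_true <- -stats::cov2cor(prec)
  diag(P_true) <- 0
  # the latent continuous block converges to the planted partials
  P_lat <- -stats::cov2cor(solve(cor(gen$latent$mother_T1)))
  diag(P_lat) <- 0
  expect_lt(max(abs(P_lat - P_true)), 0.05)
  # round-and-clamp discretisation attenuates them only mildly (the
  # 6-point well-being scales are the coarsest, hence the wider band)
  X <- stratify(gen$cohort)$mother_T1$data[, sq_subscales()]
  P_hat <- -stats::cov2cor(solve(cor(X)))
  diag(P_hat) <- 0
  expect_lt(max(abs(P_hat - P_true)), 0.1)
})

test_that("dyadic and temporal coupling show up in the latent scores", {
  prec <- diag(8)
  spec <- uniform_spec(prec, n_dyads = 4000, seed = 5,
                       dyad_rho = 0.5, time_rho = 0.6)
  strata <- stratify(generate_cohort(spec)$cohort)
  r_role <- cor(strata$mother_T1$data[, "Anxiety"],
                strata$father_T1$data[, "Anxiety"])
  r_time <- cor(strata$mother_T1$data[, "Anxiety"],
                strata$mother_T2$data[, "Anxiety"])
  # discretisation attenuates the latent correlations slightly
  expect_gt(r_role, 0.4)
  expect_gt(r_time, 0.5)
})
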