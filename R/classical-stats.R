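## Classical statistical arm: normality screening, repeated-measures and
## one-way ANOVA with Tukey HSD post hocs, a priori power analysis for the
## bivariate-normal correlation test, and classification of sample means
## against a published control norm.

test_result <- function(label, statistic, df, p_value) {
  structure(list(label = label, statistic = statistic, df = df,
                 p_value = p_value),
            class = "distressnet_test")
}

#' @export
print.distressnet_test <- function(x, ...) {
  cat(x$label, ": statistic = ", format(x$statistic, digits = 4),
      if (length(x$df)) paste0(", df = (", paste(format(x$df, digits = 4),
                                                 collapse = ", "), ")"),
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Kolmogorov-Smirnov one-sample normality test
#'
#' `D` is the supremum distance between the empirical CDF and a Gaussian
#' reference; by default the reference uses the sample mean and SD
#' (Lilliefors-style plug-in, which makes the nominal asymptotic p value
#' conservative -- the usual caveat applies), the asymptotic K-S
#' distribution supplies the p value.
#'
#' @param x Numeric sample (`n >= 1`, non-constant unless the reference is
#'   supplied explicitly).
#' @param mean,sd Optional fixed reference parameters; when omitted they
#'   are estimated from `x`.
#' @return A test result with `statistic` = D and `p_value`.
#' @export
ks_normality <- function(x, mean = NULL, sd = NULL) {
  stopifnot(length(x) >= 1)
  if (is.null(mean) || is.null(sd)) {
    if (length(x) < 2 || stats::var(x) == 0) {
      stop("cannot fit a Gaussian reference to a (near) constant sample; ",
           "supply mean and sd explicitly")
    }
    mean <- base::mean(x)
    sd <- stats::sd(x)
  }
  stopifnot(sd > 0)
  kt <- suppressWarnings(ks.test(x, "pnorm", mean, sd, exact = FALSE))
  test_result("Kolmogorov-Smirnov normality", unname(kt$statistic),
              numeric(0), unname(kt$p.value))
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject decomposition for a complete subjects-by-times score
#' matrix: `F = MS_time / MS_(time x subject)` with
#' `df = (t - 1, (t - 1)(n - 1))`. No sphericity correction is applied by
#' default; `gg = TRUE` applies the Greenhouse-Geisser epsilon to the
#' degrees of freedom.
#'
#' @param scores Numeric matrix, rows = subjects (`n >= 2`), columns = time
#'   points (`t >= 2`), no missing cells.
#' @param gg Apply the Greenhouse-Geisser correction (default `FALSE`).
#' @return A test result carrying, additionally, `means` (per-time means),
#'   `ms_error` and `df_error` for post hoc use, and `n` (subjects).
#' @export
rm_anova <- function(scores, gg = FALSE) {
  scores <- as.matrix(scores)
  n <- nrow(scores); t <- ncol(scores)
  stopifnot(n >= 2, t >= 2, !anyNA(scores))
  grand <- mean(scores)
  time_means <- colMeans(scores)
  subj_means <- rowMeans(scores)
  ss_time <- n * sum((time_means - grand)^2)
  ss_subj <- t * sum((subj_means - grand)^2)
  ss_total <- sum((scores - grand)^2)
  ss_err <- ss_total - ss_time - ss_subj
  df_time <- t - 1
  df_err <- (t - 1) * (n - 1)
  ms_err <- ss_err / df_err
  if (ms_err <= .Machine$double.eps * abs(ss_total + 1)) {
    stop("degenerate repeated-measures decomposition: ",
         "time x subject residual mean square is zero")
  }
  df_pair <- c(df_time, df_err)
  if (gg) {
    eps <- gg_epsilon(scores)
    df_pair <- df_pair * eps
  }
  F <- (ss_time / df_time) / ms_err
  res <- test_result("repeated-measures ANOVA", F, df_pair,
                     stats::pf(F, df_pair[1], df_pair[2], lower.tail = FALSE))
  res$means <- time_means
  res$ms_error <- ms_err
  res$df_error <- df_err
  res$n <- n
  res
}

## Greenhouse-Geisser epsilon from the sample covariance of the time
## columns.
gg_epsilon <- function(scores) {
  S <- stats::cov(scores)
  k <- ncol(S)
  dbar <- mean(diag(S)); sbar <- mean(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * mean(rowMeans(S)^2) + k^2 * sbar^2)
  max(min(num / den, 1), 1 / (k - 1))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range statistic `q = |mean_i - mean_j| / sqrt(ms_error / n)`
#' with p values from the studentized-range distribution on
#' (`k` means, `df_error`) degrees of freedom.
#'
#' @param group_means Named (or unnamed) numeric vector of `k >= 2` means.
#' @param ms_error Error mean square (> 0) from the surrounding ANOVA.
#' @param n_per_group Common per-group (or per-cell) sample size.
#' @param df_error Error degrees of freedom (> 0).
#' @return Data frame with one row per unordered pair: `group_i`,
#'   `group_j`, `diff`, `q`, `p_value`.
#' @export
tukey_hsd <- function(group_means, ms_error, n_per_group, df_error) {
  k <- length(group_means)
  stopifnot(k >= 2, ms_error > 0, n_per_group >= 1)
  if (!is.finite(df_error) || df_error <= 0) {
    stop("df_error must be a positive finite number")
  }
  if (is.null(names(group_means))) {
    names(group_means) <- paste0("G", seq_len(k))
  }
  se <- sqrt(ms_error / n_per_group)
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    group_i = names(group_means)[pairs[1, ]],
    group_j = names(group_means)[pairs[2, ]],
    diff = group_means[pairs[2, ]] - group_means[pairs[1, ]]
  )
  out$q <- abs(out$diff) / se
  out$p_value <- ptukey(out$q, nmeans = k, df = df_error,
                        lower.tail = FALSE)
  rownames(out) <- NULL
  out
}

#' One-way (between-groups) ANOVA
#'
#' Classical between/within sum-of-squares decomposition.
#'
#' @param groups List of `>= 2` numeric vectors, each of length `>= 2`.
#' @return A test result carrying `means`, `ms_error`, `df_error` and
#'   `n_per_group` (when balanced) for post hoc use.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 1L) >= 2))
  k <- length(groups)
  ns <- vapply(groups, length, 1L)
  all_x <- unlist(groups)
  grand <- mean(all_x)
  means <- vapply(groups, mean, 0)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1; df2 <- sum(ns) - k
  if (ss_within <= .Machine$double.eps * abs(sum(all_x^2) + 1)) {
    stop("zero within-group variance; the F statistic is undefined")
  }
  F <- (ss_between / df1) / (ss_within / df2)
  res <- test_result("one-way ANOVA", F, c(df1, df2),
                     stats::pf(F, df1, df2, lower.tail = FALSE))
  res$means <- means
  res$ms_error <- ss_within / df2
  res$df_error <- df2
  res$n_per_group <- if (length(unique(ns)) == 1) ns[1] else NA_integer_
  res
}

## Exact density of the sample correlation coefficient r given the
## population correlation rho and sample size n (bivariate normal),
## written with the Gauss hypergeometric 2F1 evaluated by its series
## (argument in [0, 1), terms decay geometrically).
hyp2f1 <- function(a, b, cc, x) {
  s <- 1; term <- 1
  for (k in 0:1000) {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * x
    s <- s + term
    if (abs(term) < 1e-16 * abs(s)) break
  }
  s
}

sample_cor_density <- function(r, rho, n) {
  ## evaluated on the log scale: the power/ratio terms under- and
  ## overflow well inside double range for n beyond ~100
  log_base <- log(n - 2) + lgamma(n - 1) - lgamma(n - 0.5) -
    0.5 * log(2 * pi) + ((n - 1) / 2) * log1p(-rho^2)
  vapply(r, function(ri) {
    one_m_r2 <- 1 - ri^2
    if (one_m_r2 <= 0) return(0)
    lf <- log_base + ((n - 4) / 2) * log(one_m_r2) -
      (n - 1.5) * log1p(-rho * ri) +
      log(hyp2f1(0.5, 0.5, n - 0.5, (rho * ri + 1) / 2))
    exp(lf)
  }, 0)
}

## P(reject H0: rho = 0) at the given population rho, using the t-based
## critical correlation and the exact sampling distribution of r.
exact_cor_power <- function(rho, n, alpha, sides) {
  df <- n - 2
  a <- if (sides == "two") alpha / 2 else alpha
  tcrit <- qt(1 - a, df)
  rc <- tcrit / sqrt(tcrit^2 + df)
  up <- integrate(sample_cor_density, rc, 1, rho = rho, n = n,
                  rel.tol = 1e-10)$value
  if (sides == "one") return(up)
  lo <- integrate(sample_cor_density, -1, -rc, rho = rho, n = n,
                  rel.tol = 1e-10)$value
  up + lo
}

fisherz_cor_power <- function(rho, n, alpha, sides) {
  df <- n - 2
  a <- if (sides == "two") alpha / 2 else alpha
  tcrit <- qt(1 - a, df)
  rc <- tcrit / sqrt(tcrit^2 + df)
  zr <- atanh(rho) + rho / (2 * (n - 1))
  zc <- atanh(rc) + rc / (2 * (n - 1))
  pnorm((zr - zc) * sqrt(n - 3))
}

#' Minimal detectable correlation of an a priori power analysis
#'
#' Inverts the power function of the test of `H0: rho = 0` for a bivariate
#' normal sample: given `n`, `alpha` and the target power, returns the
#' smallest population correlation the test detects with that power. The
#' default method integrates the exact sampling distribution of the sample
#' correlation beyond the t-based critical value; `"fisher-z"` uses the
#' bias-corrected Fisher z approximation instead (the two agree closely,
#' and converge as `n` grows). Monotone decreasing in `n`.
#'
#' @param n Sample size (`>= 4`).
#' @param alpha Significance level in (0, 1).
#' @param power Target power in (0, 1), `> alpha`.
#' @param sides `"two"` (default) or `"one"`.
#' @param method `"exact"` (default) or `"fisher-z"`.
#' @return The minimal detectable correlation, a value in (0, 1).
#' @export
#' @examples
#' power_min_r(16, alpha = 0.05, power = 0.8)  # ~0.64
power_min_r <- function(n, alpha = 0.05, power = 0.8,
                        sides = c("two", "one"),
                        method = c("exact", "fisher-z")) {
  sides <- match.arg(sides)
  method <- match.arg(method)
  if (n < 4) stop("power analysis requires n >= 4")
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  if (power <= alpha) {
    stop("target power must exceed the significance level")
  }
  pw <- switch(method, exact = exact_cor_power, `fisher-z` = fisherz_cor_power)
  uniroot(function(r) pw(r, n, alpha, sides) - power,
          interval = c(1e-6, 0.999), extendInt = "upX", tol = 1e-6)$root
}

#' Published control norm for a subscale
#'
#' @param subscale Subscale name.
#' @param control_mean Control-sample mean.
#' @param control_sd Control-sample standard deviation (> 0).
#' @return A `reference_norm` list.
#' @export
reference_norm <- function(subscale, control_mean, control_sd) {
  stopifnot(control_sd > 0)
  structure(list(subscale = subscale, control_mean = control_mean,
                 control_sd = control_sd),
            class = "reference_norm")
}

#' Classify a sample mean against a control norm
#'
#' @param sample_mean Observed mean.
#' @param norm A [reference_norm()].
#' @return `"below"` (mean < control mean - 1 SD), `"within_1sd"`, or
#'   `"above_1sd"` (mean > control mean + 1 SD).
#' @export
compare_to_reference <- function(sample_mean, norm) {
  stopifnot(inherits(norm, "reference_norm"))
  lo <- norm$control_mean - norm$control_sd
  hi <- norm$control_mean + norm$control_sd
  if (sample_mean < lo) "below"
  else if (sample_mean <= hi) "within_1sd"
  else "above_1sd"
}

#' Italian control norm for the SQ Anxiety subscale
#'
#' Control-sample anxiety norm (mean 4.25, SD 3.53) from the Italian
#' validation of the Symptom Questionnaire, the single published reference
#' value used for norm comparison.
#'
#' @return A [reference_norm()].
#' @export
sq_anxiety_norm <- function() reference_norm("Anxiety", 4.25, 3.53)

#' Classical statistics summary for a complete-case cohort
#'
#' For each subscale: K-S normality at baseline (parents pooled),
#' repeated-measures ANOVA over the three time points with Tukey post hocs
#' (subjects = individual parents), and one-way mother-vs-father ANOVAs at
#' each time point. Baseline means are classified against any supplied
#' control norms.
#'
#' @param cohort A complete-case [cohort_table()].
#' @param norms List of [reference_norm()] objects (default: the published
#'   anxiety norm).
#' @return Tidy data frame: `analysis`, `subscale`, `contrast`,
#'   `statistic`, `df1`, `df2`, `p_value`, `note`.
#' @export
cohort_stats <- function(cohort, norms = list(sq_anxiety_norm())) {
  empty <- data.frame(analysis = character(0), subscale = character(0),
                      contrast = character(0), statistic = numeric(0),
                      df1 = numeric(0), df2 = numeric(0),
                      p_value = numeric(0), note = character(0))
  if (nrow(cohort) == 0) return(empty)
  rows <- list()
  add <- function(analysis, subscale, contrast, statistic, df1, df2,
                  p_value, note = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      analysis = analysis, subscale = subscale, contrast = contrast,
      statistic = statistic, df1 = df1, df2 = df2, p_value = p_value,
      note = note)
  }
  for (s in sq_subscales()) {
    base <- cohort[cohort$time_point == "T1", s]
    kt <- try(ks_normality(base), silent = TRUE)
    if (!inherits(kt, "try-error")) {
      add("ks_normality", s, "T1 pooled", kt$statistic, NA, NA, kt$p_value)
    }
    wide <- matrix(NA_real_, 0, 3)
    for (role in parent_roles()) {
      sub <- cohort[cohort$parent_role == role, c("dyad_id", "time_point", s)]
      w <- sapply(time_points(), function(tp)
        sub[sub$time_point == tp, s][order(sub$dyad_id[sub$time_point == tp])])
      wide <- rbind(wide, w)
    }
    colnames(wide) <- time_points()
    rm <- try(rm_anova(wide), silent = TRUE)
    if (!inherits(rm, "try-error")) {
      add("rm_anova", s, "T1-T2-T3", rm$statistic, rm$df[1], rm$df[2],
          rm$p_value)
      th <- tukey_hsd(rm$means, rm$ms_error, rm$n, rm$df_error)
      for (r in seq_len(nrow(th))) {
        add("tukey_hsd", s, paste(th$group_i[r], "vs", th$group_j[r]),
            th$q[r], NA, NA, th$p_value[r])
      }
    }
    for (tp in time_points()) {
      grp <- lapply(parent_roles(), function(role)
        cohort[cohort$parent_role == role & cohort$time_point == tp, s])
      ow <- try(one_way_anova(grp), silent = TRUE)
      if (!inherits(ow, "try-error")) {
        add("one_way_anova", s, paste0("mother vs father @", tp),
            ow$statistic, ow$df[1], ow$df[2], ow$p_value)
      }
    }
  }
  for (nm in norms) {
    s <- nm$subscale
    m_t1 <- mean(cohort[cohort$time_point == "T1", s])
    add("norm_comparison", s, "T1 mean vs control", m_t1, NA, NA, NA,
        note = compare_to_reference(m_t1, nm))
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
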