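#' Construct a group summary
#'
#' A (mean, SEM, n) triple, the unit of the summary-statistics inference
#' used throughout: potencies are published as ED50 +/- SEM with the
#' probit-window n, and brain concentrations as mean +/- SD of n animals, so
#' all group comparisons must be computable from summaries alone.
#'
#' @param label character identifier.
#' @param mean group mean (mg/kg or ug/g).
#' @param sem standard error of the mean, non-negative.
#' @param n group size, integer >= 2.
#' @return Object of class `group_summary`.
#' @export
group_summary <- function(label, mean, sem, n) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(mean), length(mean) == 1L,
            is.numeric(sem), length(sem) == 1L, sem >= 0,
            length(n) == 1L, n >= 2, n == round(n))
  structure(list(label = label, mean = as.numeric(mean),
                 sem = as.numeric(sem), n = as.integer(n)),
            class = "group_summary")
}

as_group_list <- function(groups) {
  if (inherits(groups, "group_summary")) return(list(groups))
  if (is.data.frame(groups)) {
    stopifnot(all(c("label", "mean", "sem", "n") %in% names(groups)))
    return(lapply(seq_len(nrow(groups)), function(i)
      group_summary(groups$label[i], groups$mean[i], groups$sem[i],
                    groups$n[i])))
  }
  stopifnot(all(vapply(groups, inherits, TRUE, "group_summary")))
  groups
}

test_result <- function(statistic, df1, p, df2 = NULL, comparisons = NULL,
                        method = "", extra = list()) {
  structure(c(list(statistic = statistic, df1 = df1, df2 = df2, p = p,
                   comparisons = comparisons, method = method), extra),
            class = "mes_test")
}

#' @export
print.mes_test <- function(x, ...) {
  if (identical(x$method, "welch"))
    cat(sprintf("Welch t-test from summaries: t = %.3f; df = %.2f; p = %s\n",
                x$statistic, x$df1, format_p(x$p)))
  else if (identical(x$method, "anova"))
    cat(sprintf("One-way ANOVA from summaries: F(%d;%d) = %.3f; p = %s\n",
                x$df1, x$df2, x$statistic, format_p(x$p)))
  else
    cat(sprintf("%s: statistic = %.3f; p = %s\n", x$method, x$statistic,
                format_p(x$p)))
  if (!is.null(x$comparisons)) print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Welch two-sample t-test from group summaries
#'
#' Unequal-variance (Welch) comparison of two group means given only
#' (mean, SEM, n): t = |m_a - m_b| / sqrt(sem_a^2 + sem_b^2), with
#' Welch-Satterthwaite degrees of freedom
#' df = (sem_a^2 + sem_b^2)^2 / (sem_a^4/(n_a - 1) + sem_b^4/(n_b - 1)),
#' and a two-sided p from the t distribution. This is the form whose
#' fractional df match published potency-comparison tables computed from
#' printed SEMs.
#'
#' @param a,b [group_summary()] objects.
#' @return A `mes_test` with `statistic` (t), `df1` (fractional df), `p`.
#' @examples
#' welch_from_summary(group_summary("exp", 238.3, 11.48, 16),
#'                    group_summary("add", 284.8, 7.01, 36))
#' @export
welch_from_summary <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$sem == 0 && b$sem == 0) {
    if (a$mean != b$mean)
      mesiso_error("mesiso_zero_variance",
                   "both SEMs are zero but the means differ")
    return(test_result(0, a$n + b$n - 2, 1, method = "welch"))
  }
  v <- a$sem^2 + b$sem^2
  t <- abs(a$mean - b$mean) / sqrt(v)
  df <- v^2 / (a$sem^4 / (a$n - 1) + b$sem^4 / (b$n - 1))
  test_result(t, df, 2 * stats::pt(-t, df), method = "welch")
}

anova_components <- function(groups) {
  m <- vapply(groups, `[[`, 0, "mean")
  sem <- vapply(groups, `[[`, 0, "sem")
  n <- vapply(groups, `[[`, 0L, "n")
  sd <- sem * sqrt(n)
  N <- sum(n); k <- length(groups)
  gm <- sum(n * m) / N
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((n - 1) * sd^2)
  list(m = m, n = n, k = k, N = N, msb = ssb / (k - 1), msw = ssw / (N - k))
}

#' One-way ANOVA from group summaries
#'
#' Reconstructs the classic one-way ANOVA table from (mean, SEM, n) triples:
#' SD_i = sem_i * sqrt(n_i), between-group SS about the size-weighted grand
#' mean, within-group SS = sum (n_i - 1) SD_i^2, and
#' F = MSB / MSW on (k - 1, N - k) degrees of freedom. For raw data this is
#' identical to `anova(aov(...))`.
#'
#' @param groups list of [group_summary()] objects, or a data frame with
#'   columns `label`, `mean`, `sem`, `n`.
#' @return A `mes_test` with `statistic` (F), `df1`, `df2`, `p`, and `msw`
#'   (the pooled within-group mean square, reused by the post-hoc tests).
#' @examples
#' pb <- data.frame(label = c("vehicle", "scop25", "scop50"),
#'                  mean = c(28.85, 23.17, 18.71),
#'                  sem = c(1.89, 2.18, 1.88), n = 16)
#' anova_from_summary(pb)  # F(2;45) = 6.534
#' @export
anova_from_summary <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 2L)
    mesiso_error("mesiso_single_group", "ANOVA needs at least two groups")
  cp <- anova_components(groups)
  F <- cp$msb / cp$msw
  test_result(F, cp$k - 1L, stats::pf(F, cp$k - 1, cp$N - cp$k,
                                      lower.tail = FALSE),
              df2 = cp$N - cp$k, method = "anova",
              extra = list(msw = cp$msw))
}

#' Tukey-Kramer all-pairs comparisons from group summaries
#'
#' Post-hoc all-pairwise comparisons after [anova_from_summary()]: for each
#' pair, q = |m_i - m_j| / sqrt((MSW / 2) (1/n_i + 1/n_j)) referred to the
#' studentized-range distribution with k groups and N - k error df
#' (the Kramer form handles unequal n).
#'
#' @inheritParams anova_from_summary
#' @return A `mes_test` whose `comparisons` data frame has one row per pair:
#'   `group1`, `group2`, `estimate` (difference), `q`, `p_adj`.
#' @export
tukey_kramer_from_summary <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 3L)
    mesiso_error("mesiso_single_group",
                 "Tukey-Kramer needs at least three groups")
  cp <- anova_components(groups)
  labs <- vapply(groups, `[[`, "", "label")
  pairs <- utils::combn(cp$k, 2)
  cmp <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(cp$msw / 2 * (1 / cp$n[i1] + 1 / cp$n[i2]))
    q <- abs(cp$m[i1] - cp$m[i2]) / se
    data.frame(group1 = labs[i1], group2 = labs[i2],
               estimate = cp$m[i2] - cp$m[i1], q = q,
               p_adj = stats::ptukey(q, cp$k, cp$N - cp$k,
                                     lower.tail = FALSE))
  }))
  an <- anova_from_summary(groups)
  test_result(an$statistic, an$df1, an$p, df2 = an$df2, comparisons = cmp,
              method = "tukey-kramer", extra = list(msw = cp$msw))
}

#' Dunnett many-to-one comparisons from group summaries
#'
#' Compares each treatment group with a common control using the pooled
#' within-group variance: t_i = (m_i - m_0) / sqrt(MSW (1/n_i + 1/n_0)).
#' Two-sided adjusted p-values come from the equicorrelated multivariate-t
#' distribution of (T_1, ..., T_k) under the null, with correlations
#' lambda_i * lambda_j where lambda_i = sqrt(n_i / (n_i + n_0)), evaluated
#' with `mvtnorm::pmvt`. The quasi-Monte-Carlo integration runs under a
#' fixed internal RNG state (seed 20230111, absolute tolerance 1e-6), so
#' repeated calls are reproducible; with a single treatment the adjusted p
#' equals the unadjusted pooled-variance two-sample p.
#'
#' @param control a [group_summary()], the shared control group.
#' @param treatments list of [group_summary()] objects (or data frame as in
#'   [anova_from_summary()]).
#' @return A `mes_test` whose `comparisons` data frame has one row per
#'   treatment: `group`, `estimate` (treatment - control), `t`, `p_adj`.
#' @export
dunnett_from_summary <- function(control, treatments) {
  stopifnot(inherits(control, "group_summary"))
  treatments <- as_group_list(treatments)
  if (length(treatments) < 1L)
    mesiso_error("mesiso_no_treatments", "no treatment groups supplied")
  cp <- anova_components(c(list(control), treatments))
  k <- length(treatments)
  n0 <- cp$n[1]; ni <- cp$n[-1]
  df <- cp$N - cp$k
  tstat <- (cp$m[-1] - cp$m[1]) / sqrt(cp$msw * (1 / ni + 1 / n0))
  lam <- sqrt(ni / (ni + n0))
  R <- outer(lam, lam); diag(R) <- 1
  p_adj <- vapply(abs(tstat), function(tt) {
    with_preserved_rng(20230111, {
      1 - mvtnorm::pmvt(lower = rep(-tt, k), upper = rep(tt, k), df = df,
                        corr = R, algorithm =
                          mvtnorm::GenzBretz(abseps = 1e-6, maxpts = 250000))
    })
  }, 0)
  p_adj <- pmin(pmax(p_adj, 0), 1)
  cmp <- data.frame(group = vapply(treatments, `[[`, "", "label"),
                    estimate = cp$m[-1] - cp$m[1], t = tstat, p_adj = p_adj)
  test_result(max(abs(tstat)), df, min(p_adj), comparisons = cmp,
              method = "dunnett", extra = list(msw = cp$msw))
}

# evaluate expr under a fixed RNG state, restoring the caller's state
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Format a p-value for reporting
#'
#' Three decimals, with values below 1e-4 rendered as "<0.0001".
#' @param p numeric p-value(s).
#' @return character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 1e-4, "<0.0001", sprintf("%.3f", p))
}
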