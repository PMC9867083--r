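#' Construct a brain concentration group
#'
#' Per-animal total brain drug concentrations (ug/g wet tissue) for one
#' treatment arm; the design of record uses 8 separate brain preparations
#' per arm.
#'
#' @param treatment character identifier.
#' @param values numeric vector of concentrations, all positive.
#' @return Object of class `brain_conc_group`.
#' @export
brain_conc_group <- function(treatment, values) {
  stopifnot(is.character(treatment), length(treatment) == 1L,
            length(values) >= 1L, all(values > 0))
  structure(list(treatment = treatment, values = as.numeric(values)),
            class = "brain_conc_group")
}

#' Summarise a brain concentration group
#'
#' Brain-level figures report mean +/- SD; the shared summary-test machinery
#' works on SEMs, so the group is reduced to (mean, SEM = SD/sqrt(n), n).
#'
#' @param group a [brain_conc_group()].
#' @return A [group_summary()].
#' @export
summarize_brain_group <- function(group) {
  stopifnot(inherits(group, "brain_conc_group"))
  v <- group$values
  group_summary(group$treatment, mean(v), stats::sd(v) / sqrt(length(v)),
                length(v))
}

#' Percent change of brain drug concentration versus control
#'
#' (mean(treated) - mean(control)) / mean(control) * 100, rounded to the
#' nearest integer for reporting (positive values mean elevated brain
#' levels).
#'
#' @param control,treated [brain_conc_group()] objects.
#' @return Integer percent.
#' @export
percent_change_vs_control <- function(control, treated) {
  stopifnot(inherits(control, "brain_conc_group"),
            inherits(treated, "brain_conc_group"))
  if (length(control$values) == 0L || length(treated$values) == 0L)
    mesiso_error("mesiso_empty_group", "both groups must be non-empty")
  round((mean(treated$values) - mean(control$values)) /
          mean(control$values) * 100)
}

#' Compare brain drug levels across treatment arms
#'
#' One-way ANOVA over all arms followed by Dunnett many-to-one comparisons
#' against the control arm, both computed from the group summaries (so the
#' result is identical to running [anova_from_summary()] /
#' [dunnett_from_summary()] on the summarised data).
#'
#' @param control a [brain_conc_group()], the drug-alone control arm.
#' @param treatments list of [brain_conc_group()] objects.
#' @return Object of class `brain_comparison`: list with `anova`, `dunnett`
#'   (both `mes_test`), `summaries` (data frame incl. SD and percent change
#'   vs control).
#' @export
compare_brain_levels <- function(control, treatments) {
  stopifnot(inherits(control, "brain_conc_group"))
  if (inherits(treatments, "brain_conc_group")) treatments <- list(treatments)
  if (length(treatments) < 1L)
    mesiso_error("mesiso_no_treatments", "no treatment groups supplied")
  stopifnot(all(vapply(treatments, inherits, TRUE, "brain_conc_group")))
  sums <- lapply(c(list(control), treatments), summarize_brain_group)
  an <- anova_from_summary(sums)
  du <- dunnett_from_summary(sums[[1]], sums[-1])
  tab <- data.frame(
    treatment = vapply(sums, `[[`, "", "label"),
    mean = vapply(sums, `[[`, 0, "mean"),
    sd = vapply(sums, function(s) s$sem * sqrt(s$n), 0),
    n = vapply(sums, `[[`, 0L, "n"),
    pct_change = c(0, vapply(treatments, function(g)
      percent_change_vs_control(control, g), 0)),
    p_adj = c(NA_real_, du$comparisons$p_adj))
  structure(list(anova = an, dunnett = du, summaries = tab),
            class = "brain_comparison")
}

#' @export
print.brain_comparison <- function(x, ...) {
  cat(sprintf("Brain levels: ANOVA F(%d;%d) = %.3f, p = %s\n",
              x$anova$df1, x$anova$df2, x$anova$statistic,
              format_p(x$anova$p)))
  print(transform(x$summaries, mean = round(mean, 2), sd = round(sd, 2)),
        row.names = FALSE)
  invisible(x)
}
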