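#' Construct a potency summary
#'
#' The published potency of one drug: ED50 +/- SEM with the probit-window n.
#'
#' @param label character identifier.
#' @param ed50 median effective dose, mg/kg, positive.
#' @param sem standard error of the ED50, mg/kg, non-negative.
#' @param n probit-window animal count, >= 1.
#' @return Object of class `potency_summary`.
#' @export
potency_summary <- function(label, ed50, sem, n) {
  stopifnot(is.character(label), length(label) == 1L, ed50 > 0, sem >= 0,
            n >= 1, n == round(n))
  structure(list(label = label, ed50 = as.numeric(ed50),
                 sem = as.numeric(sem), n = as.integer(n)),
            class = "potency_summary")
}

#' Construct a fixed-dose adjunct component
#'
#' One adjunct drug of a fixed-dose (add-on) combination: the constant dose
#' actually given, together with the drug's own solo potency, needed to
#' express the fixed dose as a fraction of its ED50.
#'
#' @param compound character identifier.
#' @param fixed_dose constant dose in the mixture, mg/kg, >= 0.
#' @param ed50_alone the drug's solo ED50, mg/kg, positive.
#' @param sem_alone SEM of the solo ED50, mg/kg (0 when unknown).
#' @param n_alone probit-window n of the solo determination.
#' @return Object of class `fixed_dose_component`.
#' @export
fixed_dose_component <- function(compound, fixed_dose, ed50_alone,
                                 sem_alone = 0, n_alone = 16L) {
  stopifnot(is.character(compound), length(compound) == 1L,
            fixed_dose >= 0, ed50_alone > 0, sem_alone >= 0, n_alone >= 1)
  structure(list(compound = compound, fixed_dose = as.numeric(fixed_dose),
                 ed50_alone = as.numeric(ed50_alone),
                 sem_alone = as.numeric(sem_alone),
                 n_alone = as.integer(n_alone)),
            class = "fixed_dose_component")
}

#' Fraction of a drug's own ED50
#'
#' A dose expressed as a proportion of the same drug's median effective
#' dose; the building block of the isobolographic transformation (the
#' fractions of all mixture components sum to 1 under exact dose-additivity).
#'
#' @param dose dose in mg/kg, >= 0 (vectorised).
#' @param ed50 the drug's ED50 in mg/kg, positive.
#' @return dose / ed50 (dimensionless). Tables render it rounded
#'   half-away-from-zero to 2 decimals, see [round_half_up()].
#' @examples
#' fraction_of_ed50(18.71, 28.85)  # 0.6485..., prints as 0.65
#' @export
fraction_of_ed50 <- function(dose, ed50) {
  if (any(ed50 <= 0))
    mesiso_error("mesiso_nonpositive_ed50", "ed50 must be positive")
  stopifnot(all(dose >= 0))
  dose / ed50
}

#' Round half away from zero
#'
#' Commercial rounding used for the printed fraction columns (R's `round`
#' rounds half to even).
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Experimental mixture ED50 on the total-dose scale
#'
#' In a fixed-dose add-on design only the main drug's dose varies; its ED50
#' determined in the presence of the adjunct(s) is converted to the
#' total-mixture-dose scale by adding the constant adjunct doses. The SEM is
#' unchanged: the fixed doses are known constants.
#'
#' @param ed50_asm_in_combo the varied drug's ED50 in the combination, mg/kg.
#' @param sem its SEM, mg/kg.
#' @param fixed_doses numeric vector of constant adjunct doses, mg/kg.
#' @return List with `ed50_total` and `sem`.
#' @examples
#' experimental_total(18.71, 1.88, 50)  # 68.71 +/- 1.88
#' @export
experimental_total <- function(ed50_asm_in_combo, sem, fixed_doses = numeric()) {
  stopifnot(ed50_asm_in_combo >= 0, sem >= 0, all(fixed_doses >= 0))
  list(ed50_total = ed50_asm_in_combo + sum(fixed_doses), sem = sem)
}

#' Theoretical additive mixture ED50 (total-dose scale)
#'
#' Under Loewe dose-additivity the fixed adjunct doses consume the fraction
#' f = sum(d_i / ED50_i) of the mixture's protective requirement, so the
#' main drug need only supply (1 - f) of its own ED50. On the
#' total-mixture-dose scale the additive ED50 is therefore
#' sum(d_i) + (1 - f) * ED50_asm. Its variance follows by the delta method:
#' Var = (1 - f)^2 sem_asm^2 + sum((ED50_asm d_i / ED50_i^2)^2 sem_i^2).
#' The animal count attached to the additive estimate follows the
#' summary-table convention n_add = n_asm + n_adjunct - 4, with a
#' multi-adjunct mixture counting once (its own determination's n).
#'
#' @param asm a [potency_summary()] for the main (dose-varied) drug.
#' @param adjuncts a [fixed_dose_component()] or list of them.
#' @param n_adjunct override for the adjunct-side n entering `n_rule`
#'   (default: the single adjunct's `n_alone`, or the shared `n_alone` when
#'   several adjuncts agree, else the first one's).
#' @param n_rule function(n_asm, n_adjunct) giving n_add
#'   (default `n_asm + n_adjunct - 4`).
#' @return Object of class `additive_ed50`: list with `ed50_add_total`,
#'   `sem_add`, `n_add`, `adjunct_fraction` (f), `fractions` (per-adjunct),
#'   `fixed_total`, `asm`, `adjuncts`.
#' @examples
#' pb <- potency_summary("PB", 28.85, 1.89, 16)
#' sco <- fixed_dose_component("scoparone", 50, 199.8, 10.2, 16)
#' additive_ed50_total(pb, sco)  # 71.63 mg/kg total
#' @export
additive_ed50_total <- function(asm, adjuncts, n_adjunct = NULL,
                                n_rule = function(n_asm, n_adj) n_asm + n_adj - 4L) {
  stopifnot(inherits(asm, "potency_summary"))
  if (inherits(adjuncts, "fixed_dose_component")) adjuncts <- list(adjuncts)
  stopifnot(all(vapply(adjuncts, inherits, TRUE, "fixed_dose_component")))
  d <- vapply(adjuncts, `[[`, 0, "fixed_dose")
  e <- vapply(adjuncts, `[[`, 0, "ed50_alone")
  s <- vapply(adjuncts, `[[`, 0, "sem_alone")
  fr <- fraction_of_ed50(d, e)
  f <- sum(fr)
  if (length(adjuncts) > 0L && f >= 1)
    mesiso_error("mesiso_dose_exceeds_additivity",
                 sprintf(paste("the fixed adjunct doses already sum to",
                               "fraction %.3f >= 1 of additivity"), f))
  total <- sum(d) + (1 - f) * asm$ed50
  var_add <- (1 - f)^2 * asm$sem^2 + sum((asm$ed50 * d / e^2)^2 * s^2)
  if (is.null(n_adjunct)) {
    na <- vapply(adjuncts, `[[`, 0L, "n_alone")
    n_adjunct <- if (length(na) == 0L) 0L else as.integer(na[1])
  }
  n_add <- if (length(adjuncts) == 0L) asm$n
           else as.integer(n_rule(asm$n, n_adjunct))
  structure(list(ed50_add_total = total, sem_add = sqrt(var_add),
                 n_add = n_add, adjunct_fraction = f, fractions = fr,
                 fixed_total = sum(d), asm = asm, adjuncts = adjuncts),
            class = "additive_ed50")
}

#' @export
print.additive_ed50 <- function(x, ...) {
  cat(sprintf("Additive ED50 (total dose): %.4g +/- %.3g mg/kg, n = %d (adjunct fraction %.3f)\n",
              x$ed50_add_total, x$sem_add, x$n_add, x$adjunct_fraction))
  invisible(x)
}

#' Classify a fixed-dose combination as additive, synergistic or antagonistic
#'
#' Compares the experimentally determined mixture ED50 (total-dose scale)
#' with the theoretically additive one by the unequal-variance (Welch) test
#' on summaries, df by Welch-Satterthwaite with per-arm df = n - 1. A
#' non-significant difference (p >= alpha) is additivity; a significant one
#' is synergy when the experimental mixture is MORE potent (smaller total
#' ED50) than additive, antagonism otherwise.
#'
#' @param ed50_exp_total experimental mixture ED50, total-dose scale, mg/kg.
#' @param sem_exp its SEM, mg/kg.
#' @param n_exp its probit-window n.
#' @param additive an [additive_ed50_total()] result, or a list with
#'   `ed50_add_total`, `sem_add`, `n_add` (published additive values can be
#'   supplied directly this way).
#' @param alpha two-sided significance level (default 0.05).
#' @param label optional combination label (used in tables/polygonograms).
#' @param asm,adjunct_names optional drug names carried to the polygonogram.
#' @param fractions optional named numeric vector of component ED50
#'   fractions; stored with their sum.
#' @return Object of class `interaction_assessment`: list with
#'   `ed50_exp_total`, `sem_exp`, `n_exp`, `additive`, `t`, `df`, `p`,
#'   `classification`, `fractions`, `sum_of_fractions`, `alpha`, `label`,
#'   `asm`, `adjunct_names`.
#' @examples
#' add <- list(ed50_add_total = 284.8, sem_add = 7.01, n_add = 36)
#' classify_interaction(238.3, 11.48, 16, add)  # synergistic, p = 0.002
#' @export
classify_interaction <- function(ed50_exp_total, sem_exp, n_exp, additive,
                                 alpha = 0.05, label = NULL, asm = NULL,
                                 adjunct_names = NULL, fractions = NULL) {
  stopifnot(n_exp >= 2, additive$n_add >= 2, sem_exp >= 0,
            additive$sem_add >= 0)
  if (!all(is.finite(c(ed50_exp_total, sem_exp, additive$ed50_add_total,
                       additive$sem_add))))
    mesiso_error("mesiso_nonfinite_input",
                 "non-finite potency or SEM supplied to the classifier")
  wt <- welch_from_summary(
    group_summary("exp", ed50_exp_total, sem_exp, n_exp),
    group_summary("add", additive$ed50_add_total, additive$sem_add,
                  additive$n_add))
  classification <- if (wt$p >= alpha) "additive"
    else if (ed50_exp_total < additive$ed50_add_total) "synergistic"
    else "antagonistic"
  if (is.null(fractions) && inherits(additive, "additive_ed50")) {
    # experimental fraction of the main drug + the fixed adjunct fractions
    fr_asm <- fraction_of_ed50(ed50_exp_total - additive$fixed_total,
                               additive$asm$ed50)
    fractions <- c(stats::setNames(fr_asm, additive$asm$label),
                   stats::setNames(additive$fractions,
                                   vapply(additive$adjuncts, `[[`, "",
                                          "compound")))
    if (is.null(asm)) asm <- additive$asm$label
    if (is.null(adjunct_names))
      adjunct_names <- vapply(additive$adjuncts, `[[`, "", "compound")
  }
  structure(list(ed50_exp_total = ed50_exp_total, sem_exp = sem_exp,
                 n_exp = as.integer(n_exp), additive = additive,
                 t = wt$statistic, df = wt$df1, p = wt$p,
                 classification = classification, fractions = fractions,
                 sum_of_fractions = if (is.null(fractions)) NULL
                                    else sum(fractions),
                 alpha = alpha, label = label, asm = asm,
                 adjunct_names = adjunct_names),
            class = "interaction_assessment")
}

#' @export
print.interaction_assessment <- function(x, ...) {
  cat(sprintf("%s: ED50exp %.4g +/- %.3g (n %d) vs ED50add %.4g +/- %.3g (n %d)\n",
              if (is.null(x$label)) "Combination" else x$label,
              x$ed50_exp_total, x$sem_exp, x$n_exp,
              x$additive$ed50_add_total, x$additive$sem_add,
              x$additive$n_add))
  cat(sprintf("  t = %.3f; df = %.2f; p = %s -> %s\n", x$t, x$df,
              format_p(x$p), x$classification))
  if (!is.null(x$fractions))
    cat("  fractions:", sum_of_fractions_string(x$fractions), "\n")
  invisible(x)
}

#' Percent change in potency
#'
#' Reduction of a drug's ED50 by an add-on treatment, as the percentage
#' (1 - ED50_combo / ED50_alone) * 100, rounded to the nearest integer for
#' reporting (positive values mean the combination is more potent).
#'
#' @param ed50_alone baseline ED50, mg/kg, positive.
#' @param ed50_combo ED50 in the combination, mg/kg.
#' @return Integer percent.
#' @examples
#' percent_change_in_potency(28.85, 18.71)  # 35
#' @export
percent_change_in_potency <- function(ed50_alone, ed50_combo) {
  if (any(ed50_alone <= 0))
    mesiso_error("mesiso_nonpositive_baseline",
                 "baseline ED50 must be positive")
  round((1 - ed50_combo / ed50_alone) * 100)
}

#' Build a polygonogram from interaction assessments
#'
#' A polygonogram is a graph whose nodes are the drugs (and fixed-dose
#' adjunct mixtures) and whose edges connect each main drug with its adjunct
#' (set), coloured by the interaction call: black for additive, red for
#' synergistic (blue for antagonistic). Nodes are ordered lexicographically
#' so the layout is deterministic.
#'
#' @param assessments list of [classify_interaction()] results, each
#'   carrying `asm` and `adjunct_names`.
#' @return Object of class `polygonogram`: list with `nodes` (sorted
#'   character vector) and `edges` (data frame `from`, `to`,
#'   `classification`, `colour`, `label`).
#' @export
build_polygonogram <- function(assessments) {
  stopifnot(all(vapply(assessments, inherits, TRUE,
                       "interaction_assessment")))
  if (length(assessments) == 0L)
    return(structure(list(nodes = character(),
                          edges = data.frame(from = character(),
                                             to = character(),
                                             classification = character(),
                                             colour = character(),
                                             label = character())),
                     class = "polygonogram"))
  rows <- lapply(assessments, function(a) {
    if (is.null(a$asm) || is.null(a$adjunct_names))
      stop("each assessment must name its member drugs (asm, adjunct_names)")
    mix <- paste(sort(a$adjunct_names), collapse = " + ")
    data.frame(from = a$asm, to = mix, classification = a$classification,
               colour = switch(a$classification, synergistic = "red",
                               antagonistic = "blue", "black"),
               label = if (is.null(a$label)) paste(a$asm, "+", mix)
                       else a$label)
  })
  edges <- do.call(rbind, rows)
  key <- apply(edges[, c("from", "to")], 1,
               function(r) paste(sort(r), collapse = "|"))
  if (anyDuplicated(key))
    mesiso_error("mesiso_duplicate_edge",
                 paste("duplicate assessment for drug set:",
                       key[duplicated(key)][1]))
  nodes <- sort(unique(c(edges$from, edges$to)))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "polygonogram")
}

#' @export
print.polygonogram <- function(x, ...) {
  cat(sprintf("Polygonogram: %d nodes, %d edges (%d synergistic)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$classification == "synergistic")))
  if (nrow(x$edges))
    print(x$edges[, c("from", "to", "classification")], row.names = FALSE)
  invisible(x)
}
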