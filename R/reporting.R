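#' Significance marker for a p-value
#'
#' `*`, `**`, `***` at p < 0.05, 0.01, 0.001; empty string otherwise.
#' @param p numeric p-value(s).
#' @return character vector.
#' @export
sig_marker <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "")))
}

#' Render a sum-of-fractions string
#'
#' Publication tables print the isobolographic fractions individually
#' rounded (half away from zero, 2 decimals) and summed after rounding,
#' e.g. "0.65 + 0.25 = 0.90".
#'
#' @param fractions numeric vector of component fractions.
#' @return character scalar.
#' @export
sum_of_fractions_string <- function(fractions) {
  r <- round_half_up(fractions, 2)
  sprintf("%s = %.2f", paste(sprintf("%.2f", r), collapse = " + "), sum(r))
}

#' Parse a sum-of-fractions string
#'
#' Inverse of [sum_of_fractions_string()]: returns the component fractions
#' and the printed total.
#' @param s character scalar like "0.65 + 0.25 = 0.90".
#' @return List with `fractions` (numeric vector) and `total`.
#' @export
parse_sum_of_fractions <- function(s) {
  parts <- strsplit(s, "=", fixed = TRUE)[[1]]
  stopifnot(length(parts) == 2L)
  list(fractions = as.numeric(strsplit(trimws(parts[1]), "+",
                                       fixed = TRUE)[[1]]),
       total = as.numeric(trimws(parts[2])))
}

#' Render a potency table with ANOVA line and fraction column
#'
#' Publication-style layout for one dose series of a main drug: each row
#' shows ED50 +/- SEM with a Tukey-Kramer significance marker against the
#' first (baseline) group, the probit-window n, and the fraction of the
#' baseline ED50; the one-way ANOVA line is attached as attribute `anova`.
#'
#' @param groups list of [group_summary()] objects (or data frame), first
#'   element the baseline (drug + vehicle).
#' @return Data frame with columns `label`, `ed50_sem`, `n`, `fraction`;
#'   attributes `anova` (formatted string) and `tests` (the underlying
#'   `mes_test` objects).
#' @export
render_potency_table <- function(groups) {
  groups <- as_group_list(groups)
  an <- anova_from_summary(groups)
  markers <- rep("", length(groups))
  tk <- NULL
  if (length(groups) >= 3L) {
    tk <- tukey_kramer_from_summary(groups)
    base <- groups[[1]]$label
    for (i in seq_along(groups)[-1]) {
      row <- tk$comparisons[tk$comparisons$group1 == base &
                            tk$comparisons$group2 == groups[[i]]$label, ]
      if (nrow(row)) markers[i] <- sig_marker(row$p_adj)
    }
  }
  tab <- data.frame(
    label = vapply(groups, `[[`, "", "label"),
    ed50_sem = sprintf("%s ± %s %s",
                       formatC(vapply(groups, `[[`, 0, "mean"),
                               format = "fg", digits = 4),
                       formatC(vapply(groups, `[[`, 0, "sem"),
                               format = "fg", digits = 3),
                       markers),
    n = vapply(groups, `[[`, 0L, "n"),
    fraction = sprintf("%.2f", round_half_up(
      vapply(groups, `[[`, 0, "mean") / groups[[1]]$mean, 2)))
  attr(tab, "anova") <- sprintf("F(%d;%d) = %.3f; p = %s", an$df1, an$df2,
                                an$statistic, format_p(an$p))
  attr(tab, "tests") <- list(anova = an, tukey = tk)
  tab
}

#' Render an interaction table
#'
#' Publication-style layout for a set of fixed-dose interaction
#' assessments: experimental and additive total-dose ED50s with SEMs and
#' n's, the Welch t / df / p string, the classification, and the
#' sum-of-fractions string.
#'
#' @param assessments list of [classify_interaction()] results.
#' @return Data frame, one row per combination.
#' @export
render_interaction_table <- function(assessments) {
  do.call(rbind, lapply(assessments, function(a) {
    data.frame(
      combo = if (is.null(a$label)) NA_character_ else a$label,
      ed50_exp = sprintf("%s ± %s %s",
                         formatC(a$ed50_exp_total, format = "fg", digits = 4),
                         formatC(a$sem_exp, format = "fg", digits = 3),
                         sig_marker(a$p)),
      n_exp = a$n_exp,
      ed50_add = sprintf("%s ± %s",
                         formatC(a$additive$ed50_add_total, format = "fg",
                                 digits = 4),
                         formatC(a$additive$sem_add, format = "fg",
                                 digits = 3)),
      n_add = a$additive$n_add,
      t_test = sprintf("t = %.3f; df = %.2f; p = %s", a$t, a$df,
                       format_p(a$p)),
      classification = a$classification,
      sum_of_fractions = if (is.null(a$fractions)) NA_character_
                         else sum_of_fractions_string(a$fractions))
  }))
}

#' Flat CSV of interaction assessments
#'
#' Machine-readable counterpart of [render_interaction_table()] with the
#' columns `combo,ed50_exp_total,sem_exp,n_exp,ed50_add_total,sem_add,
#' n_add,t,df,p,classification,sum_of_fractions`.
#'
#' @param assessments list of [classify_interaction()] results.
#' @param path optional output path; when given the table is also written.
#' @return The data frame (invisibly when `path` is given).
#' @export
assessment_csv <- function(assessments, path = NULL) {
  df <- do.call(rbind, lapply(assessments, function(a)
    data.frame(combo = if (is.null(a$label)) NA_character_ else a$label,
               ed50_exp_total = a$ed50_exp_total, sem_exp = a$sem_exp,
               n_exp = a$n_exp,
               ed50_add_total = a$additive$ed50_add_total,
               sem_add = a$additive$sem_add, n_add = a$additive$n_add,
               t = a$t, df = a$df, p = a$p,
               classification = a$classification,
               sum_of_fractions = if (is.null(a$fractions)) NA_real_
                                  else sum(round_half_up(a$fractions, 2)))))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    return(invisible(df))
  }
  df
}

#' Export a polygonogram in DOT format
#'
#' @param poly a [build_polygonogram()] result.
#' @param path optional file path; when `NULL` the DOT text is returned.
#' @return DOT source as a character scalar (invisibly when written).
#' @export
polygonogram_dot <- function(poly, path = NULL) {
  stopifnot(inherits(poly, "polygonogram"))
  lines <- c("graph polygonogram {",
             sprintf('  "%s";', poly$nodes),
             if (nrow(poly$edges))
               sprintf('  "%s" -- "%s" [color=%s, label="%s"];',
                       poly$edges$from, poly$edges$to, poly$edges$colour,
                       poly$edges$classification),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

pipeline_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[mesiso %s] %s", format(Sys.time(), "%H:%M:%S"),
                              sprintf(fmt, ...)))
}

#' Run the full interaction-analysis pipeline
#'
#' Reads a potency CSV (`label,ed50,sem,n`) and a JSON combination config,
#' forms the additive and experimental total-dose ED50s for every declared
#' combination, classifies each interaction, and writes the report bundle:
#' an assessment CSV, a machine-readable JSON of all results, a DOT
#' polygonogram, and (optionally) SVG isobologram/polygonogram figures.
#'
#' The combination config is a JSON object
#' `{"combinations": [{"asm": "PB", "adjuncts": ["scoparone:50"],
#' "exp": "PB+scoparone50", "add_sem": 2.44}, ...]}` where `asm`, the
#' adjunct labels and `exp` refer to rows of the potency CSV (`exp` is the
#' experimentally determined potency of the varied drug in the mixture);
#' `add_sem`/`add_n` optionally override the propagated additive SEM and n
#' with published values.
#'
#' @param potency_csv path to the potency CSV.
#' @param config path to the JSON combination config, or an equivalent list.
#' @param out_dir output directory (created if needed).
#' @param alpha significance level (in (0, 0.5]).
#' @param adjunct_ref_suffix suffix appended to an adjunct label to look up
#'   its solo potency row (default "" = label used as is).
#' @param figures write SVG figures (default TRUE).
#' @param quiet suppress progress messages.
#' @return List with `assessments`, `table` (rendered), `polygonogram`,
#'   and `files` (paths written), invisibly.
#' @export
run_pipeline <- function(potency_csv, config, out_dir, alpha = 0.05,
                         adjunct_ref_suffix = "", figures = TRUE,
                         quiet = FALSE) {
  stopifnot(alpha > 0, alpha <= 0.5)
  t0 <- Sys.time()
  pot <- read_potency_csv(potency_csv)
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = FALSE)
  combos <- config$combinations
  if (is.null(combos) || length(combos) == 0L)
    mesiso_error("mesiso_no_input", "config declares no combinations")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pipeline_log(quiet, "loaded %d potencies, %d combinations",
               length(pot), length(combos))
  need <- function(label) {
    if (is.null(pot[[label]]))
      mesiso_error("mesiso_no_input",
                   sprintf("potency label '%s' missing from %s", label,
                           potency_csv))
    pot[[label]]
  }
  assessments <- lapply(combos, function(cb) {
    asm <- need(cb$asm)
    adj <- lapply(cb$adjuncts, function(spec) {
      parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
      stopifnot(length(parts) == 2L)
      ref <- need(paste0(parts[1], adjunct_ref_suffix))
      fixed_dose_component(parts[1], as.numeric(parts[2]), ref$ed50,
                           ref$sem, ref$n)
    })
    add <- additive_ed50_total(asm, adj)
    if (!is.null(cb$add_sem)) add$sem_add <- cb$add_sem
    if (!is.null(cb$add_n)) add$n_add <- as.integer(cb$add_n)
    expref <- need(cb$exp)
    et <- experimental_total(expref$ed50, expref$sem,
                             vapply(adj, `[[`, 0, "fixed_dose"))
    label <- if (!is.null(cb$label)) cb$label else
      paste(cb$asm, "+", paste(unlist(cb$adjuncts), collapse = " + "))
    classify_interaction(et$ed50_total, et$sem, expref$n, add,
                         alpha = alpha, label = label)
  })
  poly <- build_polygonogram(assessments)
  tab <- render_interaction_table(assessments)
  files <- c(assessments = file.path(out_dir, "assessments.csv"),
             json = file.path(out_dir, "results.json"),
             dot = file.path(out_dir, "polygonogram.dot"))
  assessment_csv(assessments, files[["assessments"]])
  jsonlite::write_json(
    list(alpha = alpha,
         assessments = lapply(assessments, function(a)
           list(combo = a$label, ed50_exp_total = a$ed50_exp_total,
                sem_exp = a$sem_exp, n_exp = a$n_exp,
                ed50_add_total = a$additive$ed50_add_total,
                sem_add = a$additive$sem_add, n_add = a$additive$n_add,
                t = a$t, df = a$df, p = a$p,
                classification = a$classification,
                fractions = as.list(a$fractions),
                sum_of_fractions = a$sum_of_fractions,
                fraction_mismatch = !is.null(a$fractions) &&
                  abs(sum(a$fractions) - 1) > 0.25))),
    files[["json"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  polygonogram_dot(poly, files[["dot"]])
  if (figures) {
    fp <- file.path(out_dir, "polygonogram.svg")
    grDevices::svg(fp, width = 6, height = 6)
    plot(poly)
    grDevices::dev.off()
    files <- c(files, polygonogram_svg = fp)
    for (a in assessments) {
      if (!inherits(a$additive, "additive_ed50")) next
      fi <- file.path(out_dir, paste0("isobologram_",
                                      gsub("[^A-Za-z0-9]+", "_", a$label),
                                      ".svg"))
      grDevices::svg(fi, width = 5, height = 5)
      plot_isobologram(a)
      grDevices::dev.off()
      files <- c(files, fi)
    }
  }
  pipeline_log(quiet, "wrote %d files to %s in %.2f s", length(files),
               out_dir, as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(assessments = assessments, table = tab,
                 polygonogram = poly, files = files))
}
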