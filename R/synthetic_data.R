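#' Simulation configuration for synthetic MES experiments
#'
#' Describes the ground truth from which synthetic quantal assays,
#' fixed-dose combination assays and brain-concentration groups are drawn:
#' per-compound log10 ED50s by pretreatment time with a common probit slope,
#' dose ladders, the group size, a synergy parameter, and the
#' brain-concentration scenario.
#'
#' @param seed master integer seed; every (compound, time, dose) stream is
#'   derived deterministically from it, so adding doses or compounds never
#'   perturbs other groups.
#' @param compounds named list; each element a list with `log10_ed50` (a
#'   named numeric vector, names = pretreatment times in minutes) and
#'   `slope` (probits per log10 dose, positive).
#' @param dose_ladders optional named list of numeric dose vectors per
#'   compound; when absent, [default_dose_ladder()] builds a 4-dose
#'   geometric ladder (factor sqrt(2)) centred on the true ED50.
#' @param group_size animals per dose group (default 8).
#' @param synergy departure from dose-additivity in combinations: 0 gives
#'   exact additivity, s > 0 makes the mixture supra-additive (see
#'   [simulate_combination()]).
#' @param brain list with `control_mean` (ug/g), `ratios` (named numeric:
#'   true treated/control mean ratios), `cv` (coefficient of variation).
#' @return Object of class `sim_config`.
#' @seealso [mes_sim_config()] for the study-conditions default.
#' @export
sim_config <- function(seed, compounds, dose_ladders = NULL, group_size = 8L,
                       synergy = 0,
                       brain = list(control_mean = 20, cv = 0.10,
                                    ratios = c(scoparone = 1.00,
                                               borneol = 1.39,
                                               "scoparone+borneol" = 1.50))) {
  stopifnot(length(seed) == 1L, seed == round(seed), group_size >= 1,
            is.list(compounds), length(names(compounds)) == length(compounds))
  for (cmp in compounds)
    stopifnot(is.numeric(cmp$log10_ed50), !is.null(names(cmp$log10_ed50)),
              cmp$slope > 0)
  if (!is.null(brain$cv) && brain$cv <= 0)
    mesiso_error("mesiso_invalid_cv", "brain cv must be positive")
  structure(list(seed = as.integer(seed), compounds = compounds,
                 dose_ladders = dose_ladders,
                 group_size = as.integer(group_size),
                 synergy = synergy, brain = brain),
            class = "sim_config")
}

#' Study-conditions simulation configuration
#'
#' The default ground truth mirrors the MES study design this package
#' analyses: scoparone and borneol with time-dependent ED50s at 15/30/60/120
#' min pretreatment, the four classic antiseizure medications at their
#' standard pretreatment times, groups of 8 mice, a common probit slope of 6
#' probits per log10 dose (steep MES-type curves; yields ED50 SEMs of about
#' 6-7% with 4-dose ladders), and brain-concentration arms of n = 8 with a
#' 10% coefficient of variation.
#'
#' @param seed master integer seed.
#' @param slope probit slope shared by all compounds (default 6).
#' @param ... further arguments passed to [sim_config()].
#' @return A `sim_config`.
#' @export
mes_sim_config <- function(seed, slope = 6, ...) {
  ed <- function(x) log10(x)
  compounds <- list(
    scoparone = list(log10_ed50 = c("15" = ed(199.8), "30" = ed(277.7),
                                    "60" = ed(256.5), "120" = ed(320.1)),
                     slope = slope),
    borneol = list(log10_ed50 = c("15" = ed(255.4), "30" = ed(315.0),
                                  "60" = ed(370.8), "120" = ed(448.1)),
                   slope = slope),
    CBZ = list(log10_ed50 = c("30" = ed(9.52)), slope = slope),
    PHT = list(log10_ed50 = c("120" = ed(8.71)), slope = slope),
    PB = list(log10_ed50 = c("60" = ed(28.85)), slope = slope),
    VPA = list(log10_ed50 = c("30" = ed(292.0)), slope = slope))
  sim_config(seed, compounds, ...)
}

#' Default geometric dose ladder
#'
#' Four doses spaced by a factor sqrt(2) and centred (in log scale) on a
#' target dose — the usual titration pattern of an MES potency
#' determination.
#'
#' @param center target dose, mg/kg.
#' @param n_doses number of doses (default 4).
#' @param factor geometric spacing factor (default sqrt(2)).
#' @return Numeric dose vector.
#' @export
default_dose_ladder <- function(center, n_doses = 4L, factor = sqrt(2)) {
  k <- seq_len(n_doses) - (n_doses + 1) / 2
  center * factor^k
}

# Deterministic 31-bit sub-stream seed from the master seed and a stream
# label; a simple polynomial string hash keeps streams independent of the
# order in which they are drawn.
stream_seed <- function(seed, ...) {
  label <- paste(c(format(seed), ...), collapse = "\r")
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

lookup_compound <- function(config, compound, time) {
  cmp <- config$compounds[[compound]]
  if (is.null(cmp))
    mesiso_error("mesiso_unknown_compound_or_time",
                 sprintf("compound '%s' not in config", compound))
  mu <- cmp$log10_ed50[as.character(time)]
  if (is.na(mu))
    mesiso_error("mesiso_unknown_compound_or_time",
                 sprintf("time %s not configured for '%s'", time, compound))
  list(mu = unname(mu), beta = cmp$slope)
}

ladder_for <- function(config, compound, center) {
  lad <- config$dose_ladders[[compound]]
  if (is.null(lad)) lad <- default_dose_ladder(center)
  lad
}

draw_binomial_group <- function(config, stream_key, size, prob) {
  with_preserved_rng(stream_seed(config$seed, stream_key), {
    stats::rbinom(1L, size, prob)
  })
}

#' Simulate a quantal MES assay
#'
#' For each dose d of the compound's ladder, the number protected is drawn
#' from Binomial(group_size, Phi(beta * (log10 d - mu(time)))). Each
#' (compound, time, dose) triple has its own deterministic RNG sub-stream of
#' the master seed, so assays are reproducible and mutually independent.
#'
#' @param config a [sim_config()].
#' @param compound compound name present in the config.
#' @param time pretreatment time (minutes) configured for that compound.
#' @param doses optional explicit dose vector (defaults to the configured
#'   or default ladder centred on the true ED50).
#' @return A [quantal_assay()].
#' @export
simulate_assay <- function(config, compound, time, doses = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tr <- lookup_compound(config, compound, time)
  if (is.null(doses)) doses <- ladder_for(config, compound, 10^tr$mu)
  p <- stats::pnorm(tr$beta * (log10(doses) - tr$mu))
  y <- vapply(seq_along(doses), function(i)
    draw_binomial_group(config, paste("assay", compound, time,
                                      format(doses[i], digits = 15)),
                        config$group_size, p[i]), 0L)
  quantal_assay(compound, as.numeric(time), doses,
                rep(config$group_size, length(doses)), y)
}

#' Construct a fixed-dose combination design
#'
#' @param asm main (dose-varied) compound name.
#' @param adjuncts named numeric vector of fixed adjunct doses, mg/kg
#'   (names are compound names), all >= 0.
#' @param asm_doses optional explicit dose ladder for the main drug.
#' @return Object of class `combination_design`.
#' @export
combination_design <- function(asm, adjuncts = numeric(), asm_doses = NULL) {
  stopifnot(is.character(asm), length(asm) == 1L, all(adjuncts >= 0),
            length(adjuncts) == 0L || !is.null(names(adjuncts)))
  structure(list(asm = asm, adjuncts = adjuncts, asm_doses = asm_doses),
            class = "combination_design")
}

#' Effective ED50 of the main drug in a fixed-dose combination
#'
#' Under the generator's dose-additivity model the fixed adjunct doses
#' consume the fraction f = sum(d_i / ED50_i) of the protective requirement
#' and the main drug's effective ED50 becomes
#' ED50_asm * (1 - f * (1 + s)); the synergy parameter s = 0 recovers exact
#' Loewe additivity and s > 0 shifts the mixture beyond it.
#'
#' @param ed50_asm main drug solo ED50.
#' @param f summed adjunct fraction.
#' @param s synergy parameter.
#' @return Effective ED50 (mg/kg).
#' @export
effective_ed50 <- function(ed50_asm, f, s = 0) {
  if (f * (1 + s) >= 1)
    mesiso_error("mesiso_adjuncts_exceed_ed50",
                 sprintf("f * (1 + s) = %.3f >= 1: adjuncts alone reach the ED50",
                         f * (1 + s)))
  ed50_asm * (1 - f * (1 + s))
}

#' Simulate a fixed-dose combination assay
#'
#' The main drug is titrated in the constant presence of the adjunct doses;
#' protection at main-drug dose a follows
#' Phi(beta_asm * (log10 a - log10 ED50_eff)) with ED50_eff from
#' [effective_ed50()] (adjunct ED50s taken at `adjunct_time`). With no
#' adjuncts the draw is identical, stream for stream, to [simulate_assay()].
#'
#' @param config a [sim_config()].
#' @param design a [combination_design()].
#' @param asm_time pretreatment time of the main drug (default: its first
#'   configured time).
#' @param adjunct_time pretreatment time of the adjuncts (default 15 min,
#'   the peak-effect time of the natural compounds).
#' @return A [quantal_assay()] for the main drug's varied doses.
#' @export
simulate_combination <- function(config, design, asm_time = NULL,
                                 adjunct_time = 15) {
  stopifnot(inherits(config, "sim_config"),
            inherits(design, "combination_design"))
  if (is.null(asm_time))
    asm_time <- names(config$compounds[[design$asm]]$log10_ed50)[1]
  tr <- lookup_compound(config, design$asm, asm_time)
  f <- 0
  for (nm in names(design$adjuncts)) {
    adj <- lookup_compound(config, nm, adjunct_time)
    f <- f + design$adjuncts[[nm]] / 10^adj$mu
  }
  ed_eff <- effective_ed50(10^tr$mu, f, config$synergy)
  doses <- design$asm_doses
  if (is.null(doses)) doses <- default_dose_ladder(ed_eff)
  p <- stats::pnorm(tr$beta * (log10(doses) - log10(ed_eff)))
  key_suffix <- if (length(design$adjuncts) == 0L) character() else
    paste(names(design$adjuncts), design$adjuncts, sep = ":", collapse = ",")
  y <- vapply(seq_along(doses), function(i)
    draw_binomial_group(config,
                        paste(c("assay", design$asm, asm_time,
                                format(doses[i], digits = 15), key_suffix),
                              collapse = " "),
                        config$group_size, p[i]), 0L)
  quantal_assay(design$asm, as.numeric(asm_time), doses,
                rep(config$group_size, length(doses)), y)
}

#' Simulate brain concentration groups
#'
#' One control group at the configured control mean and one group per
#' treatment ratio, each of `group_size` draws from
#' Normal(ratio * control_mean, cv * ratio * control_mean) truncated at 0.
#'
#' @param config a [sim_config()] whose `brain` block sets `control_mean`,
#'   `ratios` and `cv`.
#' @return Named list of [brain_conc_group()] objects, first element
#'   `control`.
#' @export
simulate_brain_groups <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  b <- config$brain
  if (is.null(b$cv) || b$cv <= 0)
    mesiso_error("mesiso_invalid_cv", "brain cv must be positive")
  stopifnot(!is.null(b$ratios), !is.null(b$control_mean))
  draw <- function(name, mean) {
    vals <- with_preserved_rng(
      stream_seed(config$seed, paste("brain", name)), {
        v <- stats::rnorm(config$group_size, mean, b$cv * mean)
        while (any(v <= 0))  # truncation at 0 by resampling
          v[v <= 0] <- stats::rnorm(sum(v <= 0), mean, b$cv * mean)
        v
      })
    brain_conc_group(name, vals)
  }
  out <- c(list(control = draw("control", b$control_mean)),
           lapply(stats::setNames(names(b$ratios), names(b$ratios)),
                  function(nm) draw(nm, b$ratios[[nm]] * b$control_mean)))
  out
}

#' Run one simulated interaction study end to end
#'
#' Simulates and fits the three experiments behind a fixed-dose interaction
#' classification — the main drug alone, each adjunct alone (15 min), and
#' the combination — then forms the additive and experimental total-dose
#' ED50s and classifies the interaction. Fitted probit-window counts supply
#' the n's (falling back to the total animal count when fewer than 2 fitted
#' animals are in window).
#'
#' @param config a [sim_config()] (its `synergy` sets the truth).
#' @param design a [combination_design()].
#' @param asm_time,adjunct_time as in [simulate_combination()].
#' @param alpha significance level for the classification.
#' @return An [classify_interaction()] assessment, with the three `ed50_fit`
#'   objects attached as attribute `fits`.
#' @export
run_interaction_simulation <- function(config, design, asm_time = NULL,
                                       adjunct_time = 15, alpha = 0.05) {
  if (is.null(asm_time))
    asm_time <- names(config$compounds[[design$asm]]$log10_ed50)[1]
  fit_n <- function(fit) {
    if (fit$n_probit >= 2L) fit$n_probit else sum(fit$assay$n)
  }
  asm_fit <- fit_log_probit(simulate_assay(config, design$asm, asm_time))
  adj_fits <- lapply(names(design$adjuncts), function(nm)
    fit_log_probit(simulate_assay(config, nm, adjunct_time)))
  combo_fit <- fit_log_probit(simulate_combination(config, design,
                                                   asm_time, adjunct_time))
  asm_pot <- potency_summary(design$asm, asm_fit$ed50, asm_fit$sem,
                             fit_n(asm_fit))
  adjuncts <- lapply(seq_along(adj_fits), function(i)
    fixed_dose_component(names(design$adjuncts)[i],
                         design$adjuncts[[i]], adj_fits[[i]]$ed50,
                         adj_fits[[i]]$sem, fit_n(adj_fits[[i]])))
  add <- additive_ed50_total(asm_pot, adjuncts)
  et <- experimental_total(combo_fit$ed50, combo_fit$sem, design$adjuncts)
  out <- classify_interaction(et$ed50_total, et$sem, fit_n(combo_fit), add,
                              alpha = alpha,
                              label = paste(design$asm, "+",
                                            paste(names(design$adjuncts),
                                                  collapse = " + ")))
  attr(out, "fits") <- list(asm = asm_fit, adjuncts = adj_fits,
                            combination = combo_fit)
  out
}
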