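#' Construct a quantal assay
#'
#' A quantal assay holds the per-dose protection counts for one compound at
#' one pretreatment time: groups of animals receive increasing doses and each
#' animal is scored protected / not protected (e.g. absence of tonic hindlimb
#' extension in the maximal electroshock seizure test).
#'
#' @param compound character scalar, compound identifier.
#' @param pretreatment_min positive numeric, minutes between administration
#'   and the seizure test.
#' @param dose numeric vector of doses in mg/kg, all positive.
#' @param n integer vector, animals tested per dose group.
#' @param protected integer vector, animals protected per dose group.
#' @return An object of class `quantal_assay`: a data frame with columns
#'   `dose`, `n`, `protected` (sorted by dose) and attributes `compound`,
#'   `pretreatment_min`.
#' @examples
#' quantal_assay("PB", 60, dose = c(15, 22, 30), n = rep(8, 3),
#'               protected = c(1, 4, 7))
#' @export
quantal_assay <- function(compound, pretreatment_min, dose, n, protected) {
  stopifnot(is.character(compound), length(compound) == 1L,
            is.numeric(pretreatment_min), length(pretreatment_min) == 1L,
            pretreatment_min > 0)
  if (length(dose) != length(n) || length(n) != length(protected))
    stop("dose, n and protected must have equal length")
  if (any(dose <= 0)) stop("doses must be positive")
  if (any(n < 1) || any(n != round(n))) stop("n must be positive integers")
  if (any(protected < 0) || any(protected > n))
    stop("protected must satisfy 0 <= protected <= n")
  if (length(unique(dose)) < 2L)
    stop("a quantal assay needs at least two distinct doses")
  ord <- order(dose)
  out <- data.frame(dose = as.numeric(dose[ord]), n = as.integer(n[ord]),
                    protected = as.integer(protected[ord]))
  structure(out, compound = compound,
            pretreatment_min = as.numeric(pretreatment_min),
            class = c("quantal_assay", "data.frame"))
}

#' @export
print.quantal_assay <- function(x, ...) {
  cat(sprintf("Quantal assay: %s, pretreatment %g min\n",
              attr(x, "compound"), attr(x, "pretreatment_min")))
  print(data.frame(dose = x$dose, n = x$n, protected = x$protected,
                   pct = round(100 * x$protected / x$n)), row.names = FALSE)
  invisible(x)
}

mesiso_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "mesiso_error")))
}

# Complete separation: no partially-responding group and the all-or-none
# groups are perfectly ordered along dose (in either direction), so the
# probit likelihood is unbounded in the slope.
has_separation <- function(protected, n) {
  partial <- protected > 0L & protected < n
  if (any(partial)) return(FALSE)
  state <- as.integer(protected == n)  # 0 = none protected, 1 = all
  all(diff(state) >= 0L) || all(diff(state) <= 0L)
}

#' Fit a log-probit dose-response model to a quantal assay
#'
#' Maximum-likelihood probit regression of the per-animal protection outcome
#' on log10 dose: P(protect | d) = Phi(beta * (log10 d - mu)), where
#' 10^mu is the median effective dose ED50 and beta is the probit slope
#' (probits per log10 dose unit). The fit is the binomial GLM with probit
#' link; 95% confidence limits for the ED50 come from the delta method on mu
#' (log scale, then exponentiated) and the SEM on the mg/kg scale is derived
#' from the limits via [sem_from_cl()]. The reported `n_probit` counts the
#' animals at doses whose fitted protection probability falls between the
#' 4th and 6th probit (see [count_probit_window()]), the convention used for
#' the "n" of potency tables in MES-type studies.
#'
#' @param assay a [quantal_assay()].
#' @param conf_level confidence level for the limits (default 0.95).
#' @return An object of class `ed50_fit` with elements `ed50`, `log10_ed50`,
#'   `slope`, `sem`, `cl_lower`, `cl_upper`, `n_probit`, `vcov` (2x2
#'   covariance of (mu, beta)), `compound`, `pretreatment_min`, `assay`.
#' @section Errors:
#' Signals a condition of class `mesiso_degenerate_assay` when every group is
#' fully protected or every group fully unprotected (no information on the
#' ED50), and `mesiso_separation` when the responses are perfectly ordered
#' all-or-none with no intermediate group, so the slope MLE is unbounded.
#' @examples
#' a <- quantal_assay("PB", 60, c(100, 200, 400), rep(8, 3), c(1, 4, 7))
#' fit_log_probit(a)  # symmetric design: ED50 exactly 200 mg/kg
#' @seealso [sem_from_cl()], [count_probit_window()], [ed50_time_trend()]
#' @export
fit_log_probit <- function(assay, conf_level = 0.95) {
  stopifnot(inherits(assay, "quantal_assay"))
  y <- assay$protected; n <- assay$n; d <- assay$dose
  if (all(y == 0L) || all(y == n))
    mesiso_error("mesiso_degenerate_assay",
                 "all responses are 0% or 100%: ED50 not estimable")
  if (has_separation(y, n))
    mesiso_error("mesiso_separation",
                 sprintf(paste("complete separation (responses %s of %s):",
                               "slope MLE is unbounded"),
                         paste(y, collapse = "/"), paste(n, collapse = "/")))
  x <- log10(d)
  # steep near-separated assays trigger glm's fitted-probability warnings;
  # the estimate is validated explicitly below, so they carry no information
  fit <- suppressWarnings(
    stats::glm(cbind(y, n - y) ~ x, family = stats::binomial("probit"),
               control = stats::glm.control(epsilon = 1e-12, maxit = 200)))
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  if (!is.finite(b) || b <= 0)
    mesiso_error("mesiso_nonpositive_slope",
                 "fitted probit slope is not positive: response does not increase with dose")
  mu <- -a / b
  V <- stats::vcov(fit)
  # (mu, beta) = (-a/b, b); Jacobian rows: d mu/d(a,b), d beta/d(a,b)
  J <- rbind(c(-1 / b, a / b^2), c(0, 1))
  Vmb <- J %*% V %*% t(J)
  dimnames(Vmb) <- list(c("mu", "beta"), c("mu", "beta"))
  if (any(!is.finite(Vmb)) || Vmb[1, 1] < 0)
    mesiso_error("mesiso_separation",
                 "quasi-separation: the information matrix is singular")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_mu <- sqrt(Vmb[1, 1])
  cl <- 10^(mu + c(-1, 1) * z * se_mu)
  out <- structure(list(
    ed50 = 10^mu, log10_ed50 = mu, slope = b,
    sem = sem_from_cl(cl[1], cl[2]),
    cl_lower = cl[1], cl_upper = cl[2],
    vcov = Vmb, conf_level = conf_level,
    compound = attr(assay, "compound"),
    pretreatment_min = attr(assay, "pretreatment_min"),
    assay = assay), class = "ed50_fit")
  out$n_probit <- count_probit_window(assay, out)
  out
}

#' @export
print.ed50_fit <- function(x, ...) {
  cat(sprintf("Log-probit fit: %s (%g min)\n", x$compound,
              x$pretreatment_min))
  cat(sprintf("  ED50  %.4g mg/kg  (%.0f%% CL %.4g-%.4g, SEM %.3g)\n",
              x$ed50, 100 * x$conf_level, x$cl_lower, x$cl_upper, x$sem))
  cat(sprintf("  slope %.3g probits per log10 dose, n(probit 4-6) = %d\n",
              x$slope, x$n_probit))
  invisible(x)
}

#' Convert symmetric 95% confidence limits to a standard error
#'
#' Potencies in this literature are reported as ED50 +/- SEM; the SEM is
#' obtained from the 95% confidence interval half-width divided by the
#' normal 97.5% quantile: (upper - lower) / (2 * 1.959964).
#'
#' @param cl_lower,cl_upper confidence limits (same units as the estimate).
#' @return Standard error on the same scale.
#' @examples
#' sem_from_cl(18.0, 25.84)  # 2.0
#' @seealso [sem_to_cl()]
#' @export
sem_from_cl <- function(cl_lower, cl_upper) {
  if (any(cl_upper < cl_lower))
    mesiso_error("mesiso_inverted_limits",
                 "cl_upper must not be below cl_lower")
  unname((cl_upper - cl_lower) / (2 * stats::qnorm(0.975)))
}

#' Convert an estimate and SEM to symmetric 95% confidence limits
#'
#' Inverse of [sem_from_cl()]: estimate -/+ 1.959964 * sem.
#'
#' @param estimate point estimate.
#' @param sem standard error, non-negative.
#' @return Numeric vector `c(cl_lower, cl_upper)`.
#' @export
sem_to_cl <- function(estimate, sem) {
  stopifnot(sem >= 0)
  z <- stats::qnorm(0.975)
  c(cl_lower = estimate - z * sem, cl_upper = estimate + z * sem)
}

#' Count animals in the 4th-to-6th probit window
#'
#' Potency tables report n as the number of animals at doses whose
#' anticonvulsant effect lies between the 4th and 6th probit, i.e. whose
#' protection probability is within one probit (one SD) of 50%:
#' [Phi(-1), Phi(+1)] ~ [0.159, 0.841]. Membership is evaluated on the
#' FITTED probabilities, which are deterministic given the fit (an observed
#' 0/8 at a dose near the window boundary would otherwise drop in and out
#' erratically).
#'
#' @param assay a [quantal_assay()].
#' @param fit an `ed50_fit` produced from that assay (or any object with
#'   `slope` and `log10_ed50`).
#' @return Integer: total animals in window-member dose groups.
#' @export
count_probit_window <- function(assay, fit) {
  p <- stats::pnorm(fit$slope * (log10(assay$dose) - fit$log10_ed50))
  lo <- stats::pnorm(-1); hi <- stats::pnorm(1)
  as.integer(sum(assay$n[p >= lo & p <= hi]))
}

#' Convert a dose from mg/kg to mmol/kg
#'
#' Cross-compound potency comparisons are made on the molar scale; a dose in
#' mg/kg divided by the molar mass in g/mol is numerically the dose in
#' mmol/kg.
#'
#' @param dose dose in mg/kg, non-negative.
#' @param molar_mass molar mass in g/mol, positive.
#' @return Dose in mmol/kg (tables print it to 3 decimals).
#' @examples
#' mgkg_to_mmolkg(199.8, mes_molar_mass["scoparone"])  # 0.969
#' @export
mgkg_to_mmolkg <- function(dose, molar_mass) {
  if (any(molar_mass <= 0))
    mesiso_error("mesiso_nonpositive_molar_mass", "molar mass must be positive")
  stopifnot(all(dose >= 0))
  dose / molar_mass
}

#' Molar masses of the studied natural compounds
#'
#' Named vector of molar masses (g/mol): scoparone (C11H10O4) and borneol
#' (C10H18O).
#' @export
mes_molar_mass <- c(scoparone = 206.20, borneol = 154.25)

#' Linear time trend of ED50 across pretreatment times
#'
#' Tests whether a compound's ED50 changes linearly with pretreatment time
#' (a declining anticonvulsant effect shows as an increasing ED50). Fits a
#' weighted least-squares line of ED50 on time, weights 1/sem^2 (equal
#' weights when any SEM is missing or zero), and reports the two-sided
#' t-test of zero slope on k - 2 degrees of freedom.
#'
#' @param time numeric vector of pretreatment times (minutes), length >= 3.
#' @param ed50 numeric vector of ED50 estimates (mg/kg).
#' @param sem optional numeric vector of SEMs; `NULL` for equal weights.
#' @param alpha significance level used to call the direction (default 0.05).
#' @return An object of class `trend_result`: list with `slope` (mg/kg per
#'   minute), `intercept`, `slope_se`, `p_value`, `direction` (one of
#'   "increasing", "decreasing", "flat").
#' @examples
#' ed50_time_trend(c(15, 30, 60, 120), c(199.8, 277.7, 256.5, 320.1))
#' @export
ed50_time_trend <- function(time, ed50, sem = NULL, alpha = 0.05) {
  if (length(time) < 3L)
    mesiso_error("mesiso_insufficient_timepoints",
                 "trend test needs at least 3 time points")
  stopifnot(length(ed50) == length(time))
  w <- NULL
  if (!is.null(sem) && !anyNA(sem) && all(sem > 0)) w <- 1 / sem^2
  fit <- if (is.null(w)) stats::lm(ed50 ~ time)
         else stats::lm(ed50 ~ time, weights = w)
  # an exactly collinear series has ~zero residual variance; the summary is
  # still the right object, only its warning is noise here
  cf <- suppressWarnings(summary(fit))$coefficients
  slope <- cf["time", "Estimate"]; se <- cf["time", "Std. Error"]
  p <- cf["time", "Pr(>|t|)"]
  # a perfect line has residual variance 0 and an NaN p; call it by sign
  if (is.nan(p)) p <- if (abs(slope) > 0) 0 else 1
  direction <- if (p >= alpha) "flat" else if (slope > 0) "increasing"
               else "decreasing"
  structure(list(slope = unname(slope),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 slope_se = unname(se), p_value = unname(p),
                 direction = direction), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("ED50 time trend: slope %.4g mg/kg per min (SE %.3g), p = %s -> %s\n",
              x$slope, x$slope_se, format_p(x$p_value), x$direction))
  invisible(x)
}
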