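#' Read quantal assays from CSV
#'
#' Expects the header `compound,pretreatment_min,dose_mg_per_kg,n,protected`
#' (UTF-8, comma separator, dot decimal) and splits the rows into one
#' [quantal_assay()] per (compound, pretreatment time).
#'
#' @param path CSV file path.
#' @return Named list of `quantal_assay` objects (names
#'   `"compound@time"`).
#' @export
read_assay_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("compound", "pretreatment_min", "dose_mg_per_kg", "n", "protected")
  if (!all(req %in% names(df)))
    mesiso_error("mesiso_malformed_csv",
                 paste("assay CSV must have columns:",
                       paste(req, collapse = ", ")))
  if (nrow(df) == 0L)
    mesiso_error("mesiso_no_input", "assay CSV contains no rows")
  key <- paste0(df$compound, "@", df$pretreatment_min)
  lapply(split(df, key), function(d)
    quantal_assay(d$compound[1], d$pretreatment_min[1], d$dose_mg_per_kg,
                  d$n, d$protected))
}

#' Write quantal assays to CSV
#'
#' Inverse of [read_assay_csv()].
#' @param assays list of [quantal_assay()] objects (or a single one).
#' @param path output path.
#' @export
write_assay_csv <- function(assays, path) {
  if (inherits(assays, "quantal_assay")) assays <- list(assays)
  rows <- do.call(rbind, lapply(assays, function(a)
    data.frame(compound = attr(a, "compound"),
               pretreatment_min = attr(a, "pretreatment_min"),
               dose_mg_per_kg = a$dose, n = a$n, protected = a$protected)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write ED50 estimates to CSV
#'
#' One row per fit with the columns
#' `compound,pretreatment_min,ed50,sem,cl_lower,cl_upper,slope,n_probit`.
#' @param fits list of `ed50_fit` objects (or one).
#' @param path output path.
#' @export
write_ed50_csv <- function(fits, path) {
  if (inherits(fits, "ed50_fit")) fits <- list(fits)
  rows <- do.call(rbind, lapply(fits, function(f)
    data.frame(compound = f$compound, pretreatment_min = f$pretreatment_min,
               ed50 = f$ed50, sem = f$sem, cl_lower = f$cl_lower,
               cl_upper = f$cl_upper, slope = f$slope,
               n_probit = f$n_probit)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise ED50 estimates to JSON
#'
#' @param fits list of `ed50_fit` objects (or one).
#' @return JSON string mirroring the estimate fields (incl. the (mu, beta)
#'   covariance).
#' @export
ed50_to_json <- function(fits) {
  if (inherits(fits, "ed50_fit")) fits <- list(fits)
  jsonlite::toJSON(lapply(fits, function(f)
    list(compound = f$compound, pretreatment_min = f$pretreatment_min,
         ed50 = f$ed50, log10_ed50 = f$log10_ed50, slope = f$slope,
         sem = f$sem, cl_lower = f$cl_lower, cl_upper = f$cl_upper,
         n_probit = f$n_probit, vcov = unclass(f$vcov))),
    auto_unbox = TRUE, digits = NA)
}

#' Read potency summaries from CSV
#'
#' Expects columns `label,ed50,sem,n`.
#' @param path CSV path.
#' @return Named list of [potency_summary()] objects.
#' @export
read_potency_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("label", "ed50", "sem", "n")
  if (!all(req %in% names(df)))
    mesiso_error("mesiso_malformed_csv",
                 paste("potency CSV must have columns:",
                       paste(req, collapse = ", ")))
  if (nrow(df) == 0L)
    mesiso_error("mesiso_no_input", "potency CSV contains no rows")
  out <- lapply(seq_len(nrow(df)), function(i)
    potency_summary(df$label[i], df$ed50[i], df$sem[i], df$n[i]))
  stats::setNames(out, df$label)
}

#' Read brain concentration groups from long-format CSV
#'
#' Expects columns `treatment,animal_id,conc_ug_per_g`.
#' @param path CSV path.
#' @return Named list of [brain_conc_group()] objects.
#' @export
read_brain_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("treatment", "animal_id", "conc_ug_per_g")
  if (!all(req %in% names(df)))
    mesiso_error("mesiso_malformed_csv",
                 paste("brain CSV must have columns:",
                       paste(req, collapse = ", ")))
  if (nrow(df) == 0L)
    mesiso_error("mesiso_no_input", "brain CSV contains no rows")
  lapply(split(df, df$treatment), function(d)
    brain_conc_group(d$treatment[1], d$conc_ug_per_g))
}

#' Write brain concentration groups to long-format CSV
#' @param groups list of [brain_conc_group()] objects.
#' @param path output path.
#' @export
write_brain_csv <- function(groups, path) {
  rows <- do.call(rbind, lapply(groups, function(g)
    data.frame(treatment = g$treatment,
               animal_id = seq_along(g$values),
               conc_ug_per_g = g$values)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
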