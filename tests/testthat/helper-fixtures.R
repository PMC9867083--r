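# Published summary statistics used as test inputs, re-entered as code.

# Solo and add-on potency series: ED50 +/- SEM (mg/kg), probit-window n.
potency_series <- list(
  pb_scoparone = data.frame(
    label = c("PB + vehicle", "PB + scoparone (25)", "PB + scoparone (50)"),
    mean = c(28.85, 23.17, 18.71), sem = c(1.89, 2.18, 1.88), n = 16),
  cbz_scoparone = data.frame(
    label = c("CBZ + vehicle", "CBZ + scoparone (25)", "CBZ + scoparone (50)"),
    mean = c(9.52, 8.44, 6.84), sem = c(0.76, 0.84, 0.85), n = 16),
  vpa_borneol = data.frame(
    label = c("VPA + vehicle", "VPA + borneol (12.5)", "VPA + borneol (25)",
              "VPA + borneol (50)"),
    mean = c(292.0, 230.4, 205.2, 188.3), sem = c(12.6, 11.3, 11.7, 11.5),
    n = c(24, 16, 16, 16)))

# Solo potencies entering the additive predictions.
solo_ed50 <- c(CBZ = 9.52, PHT = 8.71, PB = 28.85, VPA = 292.0,
               scoparone = 199.8, borneol = 255.4)  # 15-min adjunct values
solo_sem <- c(CBZ = 0.76, PHT = 0.95, PB = 1.89, VPA = 12.6)
solo_n <- c(CBZ = 16, PHT = 16, PB = 16, VPA = 24)

# Two-drug interaction rows: experimental and (published) additive totals.
two_drug_rows <- data.frame(
  asm = c("CBZ", "PHT", "PB", "VPA", "CBZ", "PHT", "PB", "VPA"),
  adjunct = c(rep("scoparone", 4), rep("borneol", 4)),
  fixed_dose = 50,
  exp = c(56.84, 57.27, 68.71, 269.4, 57.27, 56.84, 69.57, 238.3),
  sem_exp = c(0.85, 0.72, 1.88, 12.96, 0.72, 0.85, 2.15, 11.48),
  n_exp = c(16, 16, 16, 24, 16, 16, 24, 16),
  add = c(57.14, 56.53, 71.63, 268.9, 57.66, 57.00, 73.20, 284.8),
  sem_add = c(2.01, 2.08, 2.44, 6.44, 2.26, 2.33, 2.71, 7.01),
  n_add = c(28, 28, 28, 36, 28, 28, 28, 36),
  t = c(0.138, 0.336, 0.948, 0.035, 0.164, 0.065, 1.049, 3.457),
  df = c(35.48, 33.01, 41.96, 34.38, 32.16, 33.59, 48.93, 26.68),
  add_digits = c(2, 2, 2, 1, 2, 2, 2, 1))

# Three-drug rows (scoparone 25 + borneol 25); additive values are inputs.
three_drug_rows <- data.frame(
  asm = c("CBZ", "PHT", "PB", "VPA"),
  exp = c(56.40, 55.21, 66.55, 224.1),
  sem_exp = c(0.87, 0.70, 2.40, 11.01),
  n_exp = c(16, 16, 16, 24),
  add = c(58.46, 57.74, 75.64, 288.4),
  sem_add = c(2.26, 2.34, 2.76, 7.51),
  n_add = c(28, 28, 28, 36),
  t = c(0.851, 1.036, 2.485, 4.825),
  df = c(34.24, 31.59, 41.04, 43.23))

scoparone_time_course <- data.frame(
  time = c(15, 30, 60, 120), ed50 = c(199.8, 277.7, 256.5, 320.1))

classify_row <- function(r) {
  classify_interaction(r$exp, r$sem_exp, r$n_exp,
                       list(ed50_add_total = r$add, sem_add = r$sem_add,
                            n_add = r$n_add),
                       asm = r$asm,
                       adjunct_names = strsplit(r$adjunct, "\\+")[[1]],
                       label = paste(r$asm, "+", r$adjunct))
}
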