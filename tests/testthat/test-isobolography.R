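test_that("fractions of ED50 reproduce the printed fraction column", {
  expect_equal(round_half_up(fraction_of_ed50(18.71, 28.85), 2), 0.65)
  expect_equal(round_half_up(fraction_of_ed50(50, 199.8), 2), 0.25)
  expect_equal(fraction_of_ed50(0, 123), 0)
  expect_error(fraction_of_ed50(10, 0), class = "mesiso_nonpositive_ed50")
})

test_that("experimental totals add the fixed doses and keep the SEM", {
  et <- experimental_total(18.71, 1.88, 50)
  expect_equal(et$ed50_total, 68.71)
  expect_equal(et$sem, 1.88)
  et2 <- experimental_total(6.84, 0.85, 50)
  expect_equal(et2$ed50_total, 56.84)
  et3 <- experimental_total(12.3, 0.7)
  expect_equal(et3$ed50_total, 12.3)
})

test_that("additive totals reproduce all eight published two-drug values", {
  for (i in seq_len(nrow(two_drug_rows))) {
    r <- two_drug_rows[i, ]
    add <- additive_ed50_total(
      potency_summary(r$asm, solo_ed50[[r$asm]], solo_sem[[r$asm]],
                      solo_n[[r$asm]]),
      fixed_dose_component(r$adjunct, r$fixed_dose,
                           solo_ed50[[r$adjunct]], 0, 16))
    expect_equal(round(add$ed50_add_total, r$add_digits), r$add,
                 info = paste(r$asm, r$adjunct))
    expect_equal(add$n_add, r$n_add)
  }
})

test_that("additive total is the ASM potency when there are no adjuncts", {
  pb <- potency_summary("PB", 28.85, 1.89, 16)
  add <- additive_ed50_total(pb, list())
  expect_equal(add$ed50_add_total, 28.85)
  expect_equal(add$sem_add, 1.89)
  expect_equal(add$n_add, 16L)
  expect_equal(add$adjunct_fraction, 0)
})

test_that("additive total is linear in the ASM potency and decreases in dose", {
  sco <- fixed_dose_component("scoparone", 50, 199.8, 0, 16)
  t1 <- additive_ed50_total(potency_summary("A", 10, 1, 16), sco)$ed50_add_total
  t2 <- additive_ed50_total(potency_summary("A", 20, 1, 16), sco)$ed50_add_total
  t3 <- additive_ed50_total(potency_summary("A", 30, 1, 16), sco)$ed50_add_total
  expect_equal(t3 - t2, t2 - t1, tolerance = 1e-10)
  # ASM component shrinks toward the fixed-dose floor as the dose grows
  totals <- vapply(c(10, 50, 100, 150), function(d)
    additive_ed50_total(potency_summary("A", 28.85, 1.89, 16),
                        fixed_dose_component("s", d, 199.8, 0, 16)
                        )$ed50_add_total - d, 0)
  expect_true(all(diff(totals) < 0))
})

test_that("dose-exceeds-additivity is raised when fractions reach one", {
  expect_error(
    additive_ed50_total(potency_summary("A", 10, 1, 16),
                        fixed_dose_component("s", 250, 199.8, 0, 16)),
    class = "mesiso_dose_exceeds_additivity")
})

test_that("delta-method additive SEM matches a finite-difference oracle", {
  # sem collapse: noise-free adjunct leaves only the scaled ASM term
  pb <- potency_summary("PB", 28.85, 1.89, 16)
  sco0 <- fixed_dose_component("scoparone", 50, 199.8, 0, 16)
  add0 <- additive_ed50_total(pb, sco0)
  expect_equal(add0$sem_add, (1 - 50 / 199.8) * 1.89, tolerance = 1e-12)
  # general case: gradient of the total-dose formula in (ED50_asm, ED50_1,
  # ED50_2), each with its own sem
  sems <- c(asm = 1.89, s1 = 10.2, s2 = 14.7)
  d <- c(s1 = 50, s2 = 25)
  total_fn <- function(e) sum(d) + (1 - d[1] / e[2] - d[2] / e[3]) * e[1]
  e0 <- c(28.85, 199.8, 255.4)
  g <- fd_grad(total_fn, e0)
  sem_fd <- sqrt(sum((g * sems)^2))
  add <- additive_ed50_total(
    potency_summary("PB", e0[1], sems[1], 16),
    list(fixed_dose_component("s1", d[1], e0[2], sems[2], 16),
         fixed_dose_component("s2", d[2], e0[3], sems[3], 16)))
  expect_equal(add$sem_add, sem_fd, tolerance = 1e-6)
})

test_that("interaction classification reproduces the published t-tests", {
  syn <- classify_interaction(238.3, 11.48, 16,
                              list(ed50_add_total = 284.8, sem_add = 7.01,
                                   n_add = 36))
  expect_equal(syn$t, 3.457, tolerance = 5e-4)
  expect_equal(syn$df, 26.68, tolerance = 5e-3)
  expect_identical(syn$classification, "synergistic")
  addl <- classify_interaction(56.84, 0.85, 16,
                               list(ed50_add_total = 57.14, sem_add = 2.01,
                                    n_add = 28))
  expect_equal(addl$t, 0.1375, tolerance = 1e-3)
  expect_equal(addl$df, 35.48, tolerance = 5e-3)
  expect_identical(addl$classification, "additive")
  eq <- classify_interaction(50, 1, 16, list(ed50_add_total = 50,
                                             sem_add = 1, n_add = 16))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  expect_identical(eq$classification, "additive")
})

test_that("classification is invariant under a common dose rescale", {
  for (c_fac in c(0.1, 1, 12.5)) {
    x <- classify_interaction(c_fac * 238.3, c_fac * 11.48, 16,
                              list(ed50_add_total = c_fac * 284.8,
                                   sem_add = c_fac * 7.01, n_add = 36))
    expect_identical(x$classification, "synergistic")
    expect_equal(x$t, 3.457, tolerance = 5e-4)
  }
})

test_that("zero-variance comparison of unequal means is an error", {
  expect_error(
    classify_interaction(50, 0, 16, list(ed50_add_total = 60, sem_add = 0,
                                         n_add = 16)),
    class = "mesiso_zero_variance")
})

test_that("exactly additive noise-free fractions sum to one", {
  pb <- potency_summary("PB", 28.85, 1.89, 16)
  sco <- fixed_dose_component("scoparone", 50, 199.8, 0, 16)
  add <- additive_ed50_total(pb, sco)
  x <- classify_interaction(add$ed50_add_total, add$sem_add, 28, add)
  expect_equal(x$sum_of_fractions, 1, tolerance = 1e-12)
})

test_that("percent potency changes reproduce the reported reductions", {
  expect_equal(percent_change_in_potency(28.85, 18.71), 35)
  expect_equal(percent_change_in_potency(292.0, 219.4), 25)
  expect_equal(percent_change_in_potency(100, 100), 0)
  expect_error(percent_change_in_potency(0, 5),
               class = "mesiso_nonpositive_baseline")
})

test_that("the two-drug polygonogram has eight edges, one synergistic", {
  assessments <- lapply(seq_len(nrow(two_drug_rows)), function(i)
    classify_row(two_drug_rows[i, ]))
  pg <- build_polygonogram(assessments)
  expect_equal(nrow(pg$edges), 8L)
  syn <- pg$edges[pg$edges$classification == "synergistic", ]
  expect_equal(nrow(syn), 1L)
  expect_setequal(unlist(syn[, c("from", "to")]), c("VPA", "borneol"))
  expect_identical(syn$colour, "red")
  expect_identical(pg$nodes, sort(pg$nodes))
})

test_that("the three-drug polygonogram flags PB and VPA as synergistic", {
  assessments <- lapply(seq_len(nrow(three_drug_rows)), function(i) {
    r <- three_drug_rows[i, ]
    classify_interaction(r$exp, r$sem_exp, r$n_exp,
                         list(ed50_add_total = r$add, sem_add = r$sem_add,
                              n_add = r$n_add),
                         asm = r$asm,
                         adjunct_names = c("scoparone", "borneol"))
  })
  pg <- build_polygonogram(assessments)
  expect_equal(nrow(pg$edges), 4L)
  syn <- pg$edges[pg$edges$classification == "synergistic", ]
  expect_setequal(syn$from, c("PB", "VPA"))
  expect_true(all(syn$to == "borneol + scoparone"))
})

test_that("empty and duplicated polygonogram inputs are handled", {
  pg0 <- build_polygonogram(list())
  expect_equal(length(pg0$nodes), 0L)
  expect_equal(nrow(pg0$edges), 0L)
  a <- classify_row(two_drug_rows[1, ])
  expect_error(build_polygonogram(list(a, a)),
               class = "mesiso_duplicate_edge")
})
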