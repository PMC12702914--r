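test_that("degenerate intervals swing zero and rank last; linear models match finite differences", {
  # closure linear in each parameter with known coefficients
  coef <- c(ms_prevalence = 1e4, frac_rrms = 5e5)
  closure <- function(p) sum(coef * p[names(coef)]) + 777
  specs <- tibble::tibble(
    parameter = c("ms_prevalence", "frac_rrms"),
    base = c(41, 0.8),
    low = c(41 * 0.8, 0.8),
    high = c(41 * 1.2, 0.8))
  out <- one_way_sensitivity(closure, specs)
  # +/-20% on a linear model: swing = 0.4 * base * coefficient
  fd <- (closure(c(ms_prevalence = 41 * 1.2, frac_rrms = 0.8)) -
           closure(c(ms_prevalence = 41 * 0.8, frac_rrms = 0.8)))
  expect_equal(out$swing[out$parameter == "ms_prevalence"], fd)
  expect_equal(out$swing[out$parameter == "ms_prevalence"],
               0.4 * 41 * coef[["ms_prevalence"]])
  expect_equal(out$swing[out$parameter == "frac_rrms"], 0)
  expect_equal(out$parameter[out$rank == nrow(out)], "frac_rrms")

  expect_error(one_way_sensitivity(closure,
                                   tibble::tibble(parameter = "frac_rrms",
                                                  base = 0.5, low = 0.6,
                                                  high = 0.7)),
               "low <= base <= high")
  boom <- function(p) stop("bad input")
  expect_error(one_way_sensitivity(boom, specs), "ms_prevalence")
})

test_that("cascade-level parameters outrank sub-segmentation in the fixed-course drug scenario", {
  b <- small_bundle(21)
  closure <- scenario_total_closure(
    b, list(ha_naive = c(cladribine = 1), ha_nonnaive = c(cladribine = 1)))
  tor <- one_way_sensitivity(closure, sensitivity_specs(b$cascade))
  cascade_lvl <- c("ms_prevalence", "frac_rrms", "frac_eligible")
  seg_lvl <- c("p_active", "p_ha", "p_agg", "p_naive")
  expect_gt(min(tor$swing[tor$parameter %in% cascade_lvl]),
            max(tor$swing[tor$parameter %in% seg_lvl]))
  # tornado ranking is invariant under uniform rescaling of all totals
  tor2 <- one_way_sensitivity(function(p) 3.7 * closure(p),
                              sensitivity_specs(b$cascade))
  expect_equal(tor2$parameter, tor$parameter)
})

test_that("the scenario matrix is a deterministic Cartesian product with per-cell error capture", {
  b <- small_bundle(13)
  single <- run_scenario_matrix(b, subgroups = "agg_naive",
                                uptake_modes = "full",
                                mea_selectors = "none")
  expect_equal(nrow(single), 1L)
  direct <- run_subgroup_scenario(b, "agg_naive", "full", "none")
  expect_equal(single$table[[1]]$impact, direct$impact)

  m1 <- run_scenario_matrix(b)
  m2 <- run_scenario_matrix(b)
  expect_equal(nrow(m1), 20L)
  expect_true(all(is.na(m1$error)))
  expect_identical(m1$grand_total, m2$grand_total)
  d1 <- file.path(tempdir(), "mx1"); d2 <- file.path(tempdir(), "mx2")
  write_results(m1, d1, seed = 13)
  write_results(m2, d2, seed = 13)
  expect_identical(readLines(file.path(d1, "results.csv")),
                   readLines(file.path(d2, "results.csv")))

  # a broken cell (bogus MEA variant for the multi-variant drug) is reported
  # per cell; the rest of the matrix continues
  m3 <- run_scenario_matrix(b, subgroups = c("ha_naive", "agg_naive"),
                            uptake_modes = "expert",
                            mea_selectors = c("none", "nonexistent_variant"))
  bogus <- m3$mea == "nonexistent_variant"
  expect_true(all(!is.na(m3$error[bogus])))
  expect_true(all(is.na(m3$error[!bogus])))
})

test_that("variant totals are ordered under sponsor-share-monotone contracts", {
  b <- small_bundle(17)
  # three variants monotone in BOTH cohorts' sponsor share
  b$meas$ocrelizumab <- list(
    mea1 = mea_terms("patient_split",
                     existing_groups = data.frame(patients = 400, paid_units = 3,
                                                  free_units = 1),
                     new_payer_patients = 50, new_sponsor_patients = 40),
    mea2 = mea_terms("patient_split",
                     existing_groups = data.frame(patients = c(100, 300),
                                                  paid_units = c(2, 3),
                                                  free_units = c(2, 1)),
                     new_payer_patients = 70, new_sponsor_patients = 60),
    mea3 = mea_terms("patient_split",
                     existing_groups = data.frame(patients = 400, paid_units = 2,
                                                  free_units = 2),
                     new_payer_patients = 100, new_sponsor_patients = 120))
  pop <- project_population(b$cascade, b$horizon)
  totals <- vapply(c("mea1", "mea2", "mea3"), function(v) {
    run_subgroup_scenario(b, "ha_naive", "full", mea = v,
                          featured = "ocrelizumab", pop = pop)$grand_total
  }, numeric(1))
  expect_true(totals[["mea1"]] >= totals[["mea2"]])
  expect_true(totals[["mea2"]] >= totals[["mea3"]])
})
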