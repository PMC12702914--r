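test_that("free-goods splits reduce to the enumerated free-unit fraction", {
  two_two <- mea_terms("patient_split",
                       existing_groups = data.frame(patients = 100,
                                                    paid_units = 2,
                                                    free_units = 2))
  three_one <- mea_terms("patient_split",
                         existing_groups = data.frame(patients = 300,
                                                      paid_units = 3,
                                                      free_units = 1))
  expect_equal(effective_discount(two_two, "existing"), 0.50)
  expect_equal(effective_discount(three_one, "existing"), 0.25)
  expect_equal(effective_discount(two_two, "existing"),
               enumerate_split_discount(2, 2))
  expect_equal(effective_discount(three_one, "existing"),
               enumerate_split_discount(3, 1))

  intake <- mea_terms("patient_split",
                      existing_groups = data.frame(patients = 0,
                                                   paid_units = 1,
                                                   free_units = 0),
                      new_payer_patients = 100, new_sponsor_patients = 120)
  expect_equal(effective_discount(intake, "new"), 120 / 220)

  expect_equal(effective_discount(mea_terms("fixed_discount", 0), "existing"), 0)
  expect_error(mea_terms("patient_split",
                         existing_groups = data.frame(patients = 10,
                                                      paid_units = 0,
                                                      free_units = 0)),
               "paid_units \\+ free_units")
})

test_that("mixed existing-patient groups blend by configurable headcount weights", {
  mixed <- mea_terms("patient_split",
                     existing_groups = data.frame(patients = c(100, 300),
                                                  paid_units = c(2, 3),
                                                  free_units = c(2, 1)))
  expect_equal(effective_discount(mixed, "existing"),
               (100 * 0.5 + 300 * 0.25) / 400)
  reweighted <- mea_terms("patient_split",
                          existing_groups = data.frame(patients = c(100, 300),
                                                       paid_units = c(2, 3),
                                                       free_units = c(2, 1)),
                          existing_weights = c(1, 1))
  expect_equal(effective_discount(reweighted, "existing"), (0.5 + 0.25) / 2)
})

test_that("population blend interpolates cohort discounts by spend weights", {
  t <- mea_terms("patient_split",
                 existing_groups = data.frame(patients = 1, paid_units = 2,
                                              free_units = 2),
                 new_payer_patients = 3, new_sponsor_patients = 1)
  # equal counts and prices: unweighted mean of 0.50 and 0.25
  expect_equal(blended_discount(t, 10, 10), 0.375)
  # degenerate weight: existing cohort only
  expect_equal(blended_discount(t, 10, 0), 0.5)
  expect_error(blended_discount(t, 0, 0), "zero")

  # random counts/prices vs explicit paid/free unit enumeration per patient:
  # spend-weighted blend equals (free-unit spend)/(all-unit spend)
  d_e <- enumerate_split_discount(2, 2)           # free cycles per existing patient
  patients <- c(rep("payer", 3), rep("sponsor", 1)) # annual new-patient intake
  d_n <- mean(patients == "sponsor")
  set.seed(11)
  for (i in 1:25) {
    ne <- sample(1:500, 1); nn <- sample(1:500, 1)
    pe <- round(runif(1, 100, 5000), 2); pn <- round(runif(1, 100, 5000), 2)
    sponsor_value <- ne * pe * d_e + nn * pn * d_n
    all_value <- ne * pe + nn * pn
    expect_equal(blended_discount(t, ne, nn, pe, pn), sponsor_value / all_value)
  }
})

test_that("variant sets resolve per drug and demand an explicit variant choice", {
  meas <- mea_scenario_set(
    drugA = mea_terms("fixed_discount", 0.2),
    drugB = list(mea1 = mea_terms("fixed_discount", 0.1),
                 mea2 = mea_terms("fixed_discount", 0.3)))
  expect_equal(resolve_mea(meas, "drugA", "mea1")$discount, 0.2)
  expect_equal(resolve_mea(meas, "drugB", "mea2")$discount, 0.3)
  expect_null(resolve_mea(meas, "drugC", "mea1"))
  expect_null(resolve_mea(NULL, "drugA"))
  expect_error(resolve_mea(meas, "drugB"), "variant")
  expect_error(mea_scenario_set(drugB = list(mea_terms("fixed_discount", 0.1),
                                             mea_terms("fixed_discount", 0.2))),
               "unique names|named")
})
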