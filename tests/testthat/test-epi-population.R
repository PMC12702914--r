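test_that("cascade validation names the offending field", {
  expect_error(eligibility_cascade(1e6, -1, 5, 0.8, 1), "ms_prevalence")
  expect_error(eligibility_cascade(1e6, 41, 5, 1.2, 1), "frac_rrms")
  expect_error(
    eligibility_cascade(1e6, 41, 5, 0.8, 1,
                        severity_split = c(active = 0.7, highly_active = 0.3,
                                           aggressive = 0.2)),
    "severity_split")
  expect_error(project_population(
    eligibility_cascade(1e6, 41, 5, 0.8, 1), horizon = 0), "horizon")
})

test_that("zero incidence gives counts constant across years", {
  casc <- eligibility_cascade(1e6, 41, 0, 0.8, 0.9)
  pop <- project_population(casc, 5)
  per_sub <- split(pop$counts$count, pop$counts$subgroup)
  for (s in names(per_sub)) {
    expect_equal(per_sub[[s]], rep(per_sub[[s]][1], 5))
  }
})

test_that("national prevalence of 41 per 100,000 yields 328 eligible on a 1M-adult population", {
  casc <- eligibility_cascade(
    adult_population = 1e6, ms_prevalence = 41, ms_incidence = 0,
    frac_rrms = 0.8, frac_eligible = 1,
    severity_split = c(active = 1, highly_active = 0, aggressive = 0),
    naive_split = c(active = 1, highly_active = 0.5, aggressive = 0.5))
  pop <- project_population(casc, 1)
  y1 <- pop$counts$count[pop$counts$subgroup == "active_naive" &
                           pop$counts$year == 1]
  expect_equal(round(y1), 328)
})

test_that("projection matches an independently coded per-year loop", {
  set.seed(42)
  for (i in 1:20) {
    casc <- eligibility_cascade(
      adult_population = runif(1, 1e6, 3e7),
      ms_prevalence = runif(1, 10, 80),
      ms_incidence = runif(1, 0, 10),
      frac_rrms = runif(1, 0.5, 0.95),
      frac_eligible = runif(1, 0.5, 1),
      severity_split = c(active = runif(1, 0.3, 0.5),
                         highly_active = runif(1, 0.1, 0.3),
                         aggressive = runif(1, 0.02, 0.15)),
      naive_split = c(active = 1, highly_active = runif(1),
                      aggressive = runif(1)),
      exit_rate = sample(c(0, runif(1, 0, 0.1)), 1))
    pop <- project_population(casc, 5)
    expected <- oracle_project(casc, 5)
    for (s in rownames(expected)) {
      got <- pop$counts$count[pop$counts$subgroup == s][order(
        pop$counts$year[pop$counts$subgroup == s])]
      expect_equal(got, unname(expected[s, ]), tolerance = 1e-12)
    }
  }
})

test_that("counts are homogeneous in population size and monotone in fractions", {
  base <- eligibility_cascade(2e7, 41, 5, 0.8, 0.85,
                              naive_split = c(active = 1, highly_active = 0.6,
                                              aggressive = 0.55))
  pop1 <- project_population(base, 5)$counts$count
  scaled <- eligibility_cascade(2e7 * 3.5, 41, 5, 0.8, 0.85,
                                naive_split = c(active = 1, highly_active = 0.6,
                                                aggressive = 0.55))
  expect_equal(project_population(scaled, 5)$counts$count, pop1 * 3.5)

  bumped <- eligibility_cascade(2e7, 41, 5, 0.9, 0.85,
                                naive_split = c(active = 1, highly_active = 0.6,
                                                aggressive = 0.55))
  expect_true(all(project_population(bumped, 5)$counts$count >= pop1))
})

test_that("year-over-year change is exactly the incident inflow", {
  casc <- eligibility_cascade(1.8e7, 44, 6.5, 0.8, 0.9)
  pop <- project_population(casc, 5)
  inflow_per_year <- casc$adult_population * casc$ms_incidence / 1e5
  counts <- pop$counts
  for (s in unique(counts$subgroup)) {
    cs <- counts$count[counts$subgroup == s][order(counts$year[counts$subgroup == s])]
    fac_s <- cs[2] - cs[1]   # one year's inflow for this subgroup
    for (t in 2:5) {
      expect_equal(cs[t] - cs[1], fac_s * (t - 1), tolerance = 1e-12)
    }
  }
})
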