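# Independent oracles, coded step by step against the model definitions and
# kept free of the engine code paths they check.

# per-year cascade loop: multiply the cascade factors step by step
oracle_project <- function(cascade, horizon) {
  pop <- cascade$adult_population
  if (length(pop) == 1L) pop <- rep(pop, horizon)
  sev <- cascade$severity_split
  nai <- cascade$naive_split
  fac <- c(
    active_naive = sev[["active"]] * nai[["active"]],
    ha_naive = sev[["highly_active"]] * nai[["highly_active"]],
    ha_nonnaive = sev[["highly_active"]] * (1 - nai[["highly_active"]]),
    agg_naive = sev[["aggressive"]] * nai[["aggressive"]],
    agg_nonnaive = sev[["aggressive"]] * (1 - nai[["aggressive"]]))
  out <- matrix(0, nrow = length(fac), ncol = horizon,
                dimnames = list(names(fac), NULL))
  for (s in names(fac)) {
    out[s, 1] <- pop[1] * cascade$ms_prevalence / 1e5 * cascade$frac_rrms *
      cascade$frac_eligible * fac[[s]]
    if (horizon > 1) {
      for (t in 2:horizon) {
        out[s, t] <- out[s, t - 1] * (1 - cascade$exit_rate) +
          pop[t] * cascade$ms_incidence / 1e5 * cascade$frac_rrms *
          cascade$frac_eligible * fac[[s]]
      }
    }
  }
  out
}

# decimal (integer-cent) recomputation of the five components
oracle_components <- function(profile, ty, relapse_unit_cost, discount) {
  cent <- function(x) round(x * 100)
  c(acquisition = cent((1 - discount) * profile$acquisition[ty]),
    administration = cent(profile$administration[ty] + profile$premedication[ty]),
    monitoring = cent(profile$monitoring[ty]),
    adverse_events = cent(profile$ae_cost),
    relapse = cent(profile$arr * relapse_unit_cost)) / 100
}

# per-cohort dosing timeline: prevalent cohorts sit at the first year of the
# schedule's constant tail, except fixed-course drugs whose prevalent cohort
# started its course at model year 1
oracle_treatment_year <- function(cohort, year, entry_year, profile) {
  if (cohort == "incident") return(year - entry_year + 1L)
  if (!is.null(profile$fixed_course_years)) {
    return(min(year, length(profile$acquisition)))
  }
  acq <- profile$acquisition
  m <- length(acq)
  while (m > 1L && acq[m] == acq[m - 1L]) m <- m - 1L
  m
}

# brute-force enumeration over (subgroup, cohort, drug, year, component),
# accumulating integer cents
oracle_world_expenditure <- function(pop, scenario, profiles,
                                     relapse_unit_cost,
                                     meas = NULL, sel = NULL) {
  sh <- scenario$shares
  coh <- pop$cohorts
  comps <- bia_components()
  drugs <- unique(sh$drug_id)
  acc <- array(0, dim = c(pop$horizon, length(drugs), length(comps)),
               dimnames = list(NULL, drugs, comps))
  for (i in seq_len(nrow(sh))) {
    if (sh$share[i] <= 0) next
    d <- sh$drug_id[i]
    prof <- profiles[[d]]
    terms <- if (is.null(meas)) NULL else resolve_mea(meas, d, sel)
    for (j in seq_len(nrow(coh))) {
      if (coh$subgroup[j] != sh$subgroup[i] || coh$year[j] != sh$year[i] ||
          coh$count[j] <= 0) next
      ty <- oracle_treatment_year(coh$cohort[j], coh$year[j],
                                  coh$entry_year[j], prof)
      disc <- if (is.null(terms)) 0 else
        effective_discount(terms, if (coh$cohort[j] == "prevalent")
          "existing" else "new")
      cc <- oracle_components(prof, ty, relapse_unit_cost, disc)
      for (cmp in comps) {
        acc[sh$year[i], d, cmp] <- acc[sh$year[i], d, cmp] +
          round(coh$count[j] * sh$share[i] * cc[[cmp]] * 100)
      }
    }
  }
  acc / 100
}

# max absolute difference (SAR) between a world_expenditure table and the
# enumeration oracle
world_vs_oracle <- function(w, oracle_acc) {
  got <- oracle_acc[cbind(w$year, match(w$drug_id, dimnames(oracle_acc)[[2]]),
                          match(w$component, dimnames(oracle_acc)[[3]]))]
  max(abs(got - w$value))
}

# free-goods discount via explicit unit enumeration: lay out every treatment
# unit bought in a cycle and count the free ones
enumerate_split_discount <- function(paid, free) {
  units <- c(rep("paid", paid), rep("free", free))
  sum(units == "free") / length(units)
}

small_bundle <- function(seed, ...) {
  generate_bundle(synth_config(seed = seed, ...))
}
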