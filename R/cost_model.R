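#' Per-drug cost profile by treatment year
#'
#' Unit costs per patient-year for one DMT, decomposed into the model's
#' components.  Schedules are indexed by treatment year (year on therapy,
#' not model year) so that loading doses, maintenance dosing and
#' fixed-course therapies (cladribine-style: two dosing years, then no
#' further acquisition) are representable.  Premedication is carried
#' separately but folded into administration at reporting, matching the
#' five-column decomposition of the published result tables.
#'
#' @param drug_id drug identifier.
#' @param acquisition,administration,monitoring,premedication numeric
#'   schedules of SAR per patient-year, one entry per treatment year.
#'   Scalars are recycled to the length of `acquisition`.
#' @param ae_cost SAR per patient-year for adverse-event management.
#' @param arr annualised relapse rate (relapses per patient-year); drives
#'   the relapse component as `arr * relapse_unit_cost`.
#' @param fixed_course_years for fixed-course therapies, the number of
#'   treatment years with non-zero acquisition; `NULL` otherwise.  When set,
#'   `acquisition` must be zero beyond that year.
#' @return an object of class `drug_cost_profile`.
#' @export
drug_cost_profile <- function(drug_id,
                              acquisition,
                              administration = 0,
                              monitoring = 0,
                              premedication = 0,
                              ae_cost = 0,
                              arr = 0,
                              fixed_course_years = NULL) {
  stopifnot(is.character(drug_id), length(drug_id) == 1L)
  check_nonneg(acquisition, paste0(drug_id, ".acquisition"))
  n <- length(acquisition)
  recycle <- function(x, field) {
    check_nonneg(x, paste0(drug_id, ".", field))
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n) {
      stop(sprintf("invalid value for '%s.%s': length must be 1 or match the acquisition schedule",
                   drug_id, field), call. = FALSE)
    }
    x
  }
  administration <- recycle(administration, "administration")
  monitoring <- recycle(monitoring, "monitoring")
  premedication <- recycle(premedication, "premedication")
  check_nonneg(ae_cost, paste0(drug_id, ".ae_cost"))
  check_nonneg(arr, paste0(drug_id, ".arr"))
  if (!is.null(fixed_course_years)) {
    k <- as.integer(fixed_course_years)
    if (k < 1L || k > n) {
      stop(sprintf("invalid value for '%s.fixed_course_years': must be in 1..%d",
                   drug_id, n), call. = FALSE)
    }
    if (k < n && any(acquisition[(k + 1L):n] != 0)) {
      stop(sprintf("invalid value for '%s.acquisition': must be 0 beyond fixed_course_years",
                   drug_id), call. = FALSE)
    }
    fixed_course_years <- k
  }
  structure(
    list(drug_id = drug_id,
         acquisition = acquisition,
         administration = administration,
         monitoring = monitoring,
         premedication = premedication,
         ae_cost = ae_cost,
         arr = arr,
         fixed_course_years = fixed_course_years),
    class = "drug_cost_profile"
  )
}

#' @export
print.drug_cost_profile <- function(x, ...) {
  cat("Drug cost profile:", x$drug_id,
      if (!is.null(x$fixed_course_years))
        sprintf("(fixed course, %d years)", x$fixed_course_years) else "",
      "\n")
  sched <- data.frame(treatment_year = seq_along(x$acquisition),
                      acquisition = x$acquisition,
                      administration = x$administration,
                      monitoring = x$monitoring,
                      premedication = x$premedication)
  print(sched, row.names = FALSE)
  cat(sprintf("AE cost/yr: %.2f  ARR: %.3f\n", x$ae_cost, x$arr))
  invisible(x)
}

# internal: schedule lookup, no silent extrapolation
schedule_at <- function(profile, treatment_year) {
  n <- length(profile$acquisition)
  if (treatment_year < 1 || treatment_year > n) {
    stop(sprintf("treatment year %d outside the %d-year schedule of '%s' (no extension rule declared)",
                 treatment_year, n, profile$drug_id), call. = FALSE)
  }
  as.integer(treatment_year)
}

#' First maintenance year of a dosing schedule
#'
#' The first treatment year of the longest constant tail of the acquisition
#' schedule: a loading-dose drug (year 1 priced differently, years 2+ equal)
#' has maintenance year 2; a flat schedule has maintenance year 1.  Not
#' defined for fixed-course drugs, whose prevalent cohorts follow the course
#' timeline instead.
#'
#' @param profile a [drug_cost_profile()].
#' @return integer treatment year.
#' @export
maintenance_year <- function(profile) {
  stopifnot(inherits(profile, "drug_cost_profile"))
  acq <- profile$acquisition
  m <- length(acq)
  while (m > 1L && acq[m - 1L] == acq[m]) m <- m - 1L
  as.integer(m)
}

#' Map a model year to a treatment year for a cohort
#'
#' Incident cohorts entering in model year `entry_year` are in treatment
#' year `model_year - entry_year + 1`.  Prevalent cohorts are assumed at
#' maintenance dosing (treatment year = [maintenance_year()] of the
#' schedule); for fixed-course drugs the prevalent cohort is taken to start
#' its course at model year 1, so its treatment year tracks the model year
#' (capped at the schedule length, where acquisition is already zero beyond
#' the course).
#'
#' @param cohort `"prevalent"` or `"incident"`.
#' @param model_year model year index (>= 1).
#' @param entry_year entry model year of an incident cohort.
#' @param profile the [drug_cost_profile()]; required for prevalent cohorts.
#' @return integer treatment year.
#' @export
cohort_treatment_year <- function(cohort, model_year, entry_year = 1L,
                                  profile = NULL) {
  cohort <- match.arg(cohort, c("prevalent", "incident"))
  stopifnot(model_year >= 1)
  if (cohort == "incident") {
    if (model_year < entry_year) {
      stop("model_year precedes the cohort's entry year", call. = FALSE)
    }
    return(as.integer(model_year - entry_year + 1L))
  }
  if (is.null(profile)) {
    stop("a drug cost profile is required to place a prevalent cohort",
         call. = FALSE)
  }
  if (!is.null(profile$fixed_course_years)) {
    return(as.integer(min(model_year, length(profile$acquisition))))
  }
  maintenance_year(profile)
}

#' Per-patient annual cost, decomposed into the five components
#'
#' Acquisition is the scheduled cost net of the MEA discount
#' (`(1 - mea_discount) * acquisition(treatment_year)`, rounded to the
#' cent); administration includes premedication; the relapse component is
#' `arr * relapse_unit_cost`; adverse events are a flat per-year cost.  The
#' total is the exact cent-sum of the five components.
#'
#' @param profile a [drug_cost_profile()].
#' @param treatment_year treatment year index into the schedules.
#' @param relapse_unit_cost SAR per relapse event.
#' @param mea_discount effective acquisition discount fraction in `[0, 1]`.
#' @return an object of class `component_costs`: named numeric with the five
#'   components and `total`.
#' @export
per_patient_annual_cost <- function(profile, treatment_year,
                                    relapse_unit_cost, mea_discount = 0) {
  stopifnot(inherits(profile, "drug_cost_profile"))
  check_nonneg(relapse_unit_cost, "relapse_unit_cost")
  check_fraction(mea_discount, "mea_discount")
  t <- schedule_at(profile, treatment_year)
  comp <- c(
    acquisition = round_cents((1 - mea_discount) * profile$acquisition[t]),
    administration = round_cents(profile$administration[t] + profile$premedication[t]),
    monitoring = round_cents(profile$monitoring[t]),
    adverse_events = round_cents(profile$ae_cost),
    relapse = round_cents(profile$arr * relapse_unit_cost)
  )
  out <- c(comp, total = sum_cents(comp))
  class(out) <- "component_costs"
  out
}

#' @export
print.component_costs <- function(x, ...) {
  df <- data.frame(component = names(unclass(x)),
                   sar = sprintf("%.2f", unclass(x)))
  print(df, row.names = FALSE)
  invisible(x)
}
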