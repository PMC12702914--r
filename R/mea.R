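#' Managed entry agreement (MEA) terms
#'
#' Two contract kinds are representable, both ultimately modelled as fixed
#' percentage discounts on drug acquisition costs:
#'
#' * `fixed_discount` — a straight percentage discount.
#' * `patient_split` — a free-goods scheme.  For the *existing* cohort the
#'   sponsor supplies some treatment cycles free per patient (e.g. "2 + 2":
#'   2 paid + 2 free cycles, an effective 50% discount; "3 + 1" gives 25%).
#'   Several existing-patient groups with different cycle schemes may be
#'   combined; their blend weights default to group headcounts and are
#'   configurable.  For the *new* cohort the sponsor funds a share of the
#'   annual patient intake (e.g. 100 payer vs 120 sponsor patients per year,
#'   an effective discount of 120/220).
#'
#' Performance-based contract features (relapse/MRI response criteria,
#' rebates for non-responders) are representable only through their
#' financial-equivalent fixed discount; response adjudication itself is out
#' of scope.
#'
#' @param kind `"fixed_discount"` or `"patient_split"`.
#' @param discount discount fraction for `fixed_discount`.
#' @param existing_groups data frame with columns `patients`, `paid_units`,
#'   `free_units` (one row per existing-patient group; per treatment cycle).
#' @param existing_weights optional blend weights across existing groups;
#'   defaults to `patients` headcounts.
#' @param new_payer_patients,new_sponsor_patients annual patient counts
#'   funded by the payer and the sponsor for the new cohort.
#' @return an object of class `mea_terms`.
#' @export
mea_terms <- function(kind = c("fixed_discount", "patient_split"),
                      discount = 0,
                      existing_groups = NULL,
                      existing_weights = NULL,
                      new_payer_patients = 0,
                      new_sponsor_patients = 0) {
  kind <- match.arg(kind)
  if (kind == "fixed_discount") {
    check_fraction(discount, "discount")
    return(structure(list(kind = kind, discount = discount),
                     class = "mea_terms"))
  }
  if (is.null(existing_groups)) {
    existing_groups <- data.frame(patients = 0, paid_units = 1, free_units = 0)
  }
  existing_groups <- as.data.frame(existing_groups)
  needed <- c("patients", "paid_units", "free_units")
  if (!all(needed %in% names(existing_groups))) {
    stop("invalid value for 'existing_groups': needs columns patients, paid_units, free_units",
         call. = FALSE)
  }
  for (f in needed) check_nonneg(existing_groups[[f]], paste0("existing_groups.", f))
  if (any(existing_groups$paid_units + existing_groups$free_units == 0)) {
    stop("invalid value for 'existing_groups': paid_units + free_units must be > 0",
         call. = FALSE)
  }
  check_nonneg(new_payer_patients, "new_payer_patients")
  check_nonneg(new_sponsor_patients, "new_sponsor_patients")
  if (is.null(existing_weights)) {
    existing_weights <- existing_groups$patients
  }
  check_nonneg(existing_weights, "existing_weights")
  if (length(existing_weights) != nrow(existing_groups)) {
    stop("invalid value for 'existing_weights': one weight per existing group",
         call. = FALSE)
  }
  structure(
    list(kind = kind,
         existing_groups = existing_groups,
         existing_weights = existing_weights,
         new_payer_patients = new_payer_patients,
         new_sponsor_patients = new_sponsor_patients),
    class = "mea_terms"
  )
}

#' Reduce MEA terms to an effective acquisition discount
#'
#' Fixed-discount contracts return their discount for either cohort.  For
#' patient-split contracts the existing cohort's discount is the free-goods
#' fraction `free / (paid + free)` per cycle, blended across existing-patient
#' groups by the configured weights; the new cohort's discount is the
#' sponsor-funded share of the annual intake `sponsor / (payer + sponsor)`.
#'
#' @param terms an [mea_terms()].
#' @param cohort `"existing"` or `"new"`.
#' @return discount fraction in `[0, 1]`.
#' @export
effective_discount <- function(terms, cohort = c("existing", "new")) {
  stopifnot(inherits(terms, "mea_terms"))
  cohort <- match.arg(cohort)
  if (terms$kind == "fixed_discount") {
    return(terms$discount)
  }
  if (cohort == "existing") {
    g <- terms$existing_groups
    per_group <- g$free_units / (g$paid_units + g$free_units)
    w <- terms$existing_weights
    if (sum(w) == 0) {
      # no existing patients configured: no units bought, discount moot
      return(0)
    }
    return(sum(w * per_group) / sum(w))
  }
  tot <- terms$new_payer_patients + terms$new_sponsor_patients
  if (tot == 0) {
    return(0)
  }
  terms$new_sponsor_patients / tot
}

#' Population-blended effective discount for one drug
#'
#' Weighted mean of the existing- and new-cohort discounts, weighted by
#' acquisition-cost-weighted person-years, i.e. by what each cohort would
#' have spent undiscounted.  The result always lies between the two cohort
#' discounts.
#'
#' @param terms an [mea_terms()].
#' @param existing_count,new_count person-years in each cohort (not both 0).
#' @param existing_price,new_price undiscounted per-patient acquisition cost
#'   applying to each cohort (default equal).
#' @return discount fraction in `[0, 1]`.
#' @export
blended_discount <- function(terms, existing_count, new_count,
                             existing_price = 1, new_price = 1) {
  check_nonneg(existing_count, "existing_count")
  check_nonneg(new_count, "new_count")
  check_nonneg(existing_price, "existing_price")
  check_nonneg(new_price, "new_price")
  w_e <- existing_count * existing_price
  w_n <- new_count * new_price
  if (w_e + w_n == 0) {
    stop("blended_discount: existing and new cohort weights are both zero",
         call. = FALSE)
  }
  d_e <- effective_discount(terms, "existing")
  d_n <- effective_discount(terms, "new")
  (w_e * d_e + w_n * d_n) / (w_e + w_n)
}

#' A set of MEA contracts across drugs
#'
#' One entry per drug: either a single [mea_terms()] object, or a named list
#' of variant terms for a drug negotiated under several alternative schemes
#' (the ocrelizumab-style "MEA 1 / MEA 2 / MEA 3" set).
#'
#' @param ... named arguments, one per drug: `drug_id = mea_terms(...)` or
#'   `drug_id = list(mea1 = ..., mea2 = ..., mea3 = ...)`.
#' @return an object of class `mea_scenario_set`.
#' @export
mea_scenario_set <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.null(names(entries)) &&
      is.list(entries[[1]]) && !inherits(entries[[1]], "mea_terms")) {
    entries <- entries[[1]]
  }
  if (length(entries) && (is.null(names(entries)) || any(names(entries) == ""))) {
    stop("every MEA entry must be named by its drug_id", call. = FALSE)
  }
  for (d in names(entries)) {
    e <- entries[[d]]
    if (inherits(e, "mea_terms")) next
    if (!is.list(e) || !length(e) ||
        !all(vapply(e, inherits, logical(1), "mea_terms"))) {
      stop(sprintf("MEA entry for '%s' must be mea_terms or a named list of mea_terms", d),
           call. = FALSE)
    }
    if (is.null(names(e)) || anyDuplicated(names(e))) {
      stop(sprintf("MEA variants for '%s' must have unique names", d),
           call. = FALSE)
    }
  }
  structure(entries, class = "mea_scenario_set")
}

#' Resolve the MEA terms applying to one drug
#'
#' @param meas an [mea_scenario_set()] or `NULL` (no MEAs anywhere).
#' @param drug_id drug to resolve.
#' @param select variant selector: a single name applied to every
#'   multi-variant drug (e.g. `"mea2"`), or a named character vector per
#'   drug.  Ignored for single-terms drugs.
#' @return `mea_terms` or `NULL` if the drug has no contract.
#' @export
resolve_mea <- function(meas, drug_id, select = NULL) {
  if (is.null(meas)) return(NULL)
  stopifnot(inherits(meas, "mea_scenario_set"))
  e <- meas[[drug_id]]
  if (is.null(e)) return(NULL)
  if (inherits(e, "mea_terms")) return(e)
  sel <- if (is.null(select)) NULL
         else if (!is.null(names(select))) unname(select[drug_id])
         else select
  if (is.null(sel) || is.na(sel) || !sel %in% names(e)) {
    stop(sprintf("drug '%s' has MEA variants (%s); a variant must be selected",
                 drug_id, paste(names(e), collapse = ", ")), call. = FALSE)
  }
  e[[sel]]
}
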