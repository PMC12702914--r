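#' World expenditure: population x shares x per-patient costs
#'
#' Total payer expenditure per (model year, component, drug) for one world.
#' Each cohort of each subgroup contributes
#' `count(s, cohort, y) * share(s, d, y) * per-patient component cost`,
#' where the per-patient cost is evaluated at the cohort's treatment year
#' (incident cohorts age through the dosing schedule from their entry year;
#' prevalent cohorts sit at maintenance dosing, or track the course timeline
#' for fixed-course drugs) and at the cohort's effective MEA discount
#' (prevalent = existing cohort, incident = new cohort).  Every contribution
#' is rounded to the cent before exact cent accumulation.
#'
#' @param pop a `subgroup_population` from [project_population()].
#' @param scenario a [market_scenario()].
#' @param profiles named list of [drug_cost_profile()] objects.
#' @param relapse_unit_cost SAR per relapse event.
#' @param meas optional [mea_scenario_set()]; `NULL` means no discounts.
#' @param mea_select variant selector passed to [resolve_mea()].
#' @return an object of class `world_expenditure`: tibble `year`, `drug_id`,
#'   `component`, `value` with attributes `horizon` and `world`.
#' @export
world_expenditure <- function(pop, scenario, profiles, relapse_unit_cost,
                              meas = NULL, mea_select = NULL) {
  stopifnot(inherits(pop, "subgroup_population"),
            inherits(scenario, "market_scenario"))
  shares <- scenario$shares[scenario$shares$share > 0, , drop = FALSE]
  shares <- shares[shares$subgroup %in% unique(pop$cohorts$subgroup), ,
                   drop = FALSE]
  comps <- bia_components()

  # resolve per-drug cohort discounts once
  drugs <- unique(shares$drug_id)
  disc <- list()
  for (d in drugs) {
    if (!d %in% names(profiles)) {
      sg <- shares$subgroup[match(d, shares$drug_id)]
      stop(sprintf("no cost profile for drug '%s' (shares in subgroup '%s')",
                   d, sg), call. = FALSE)
    }
    terms <- resolve_mea(meas, d, mea_select)
    disc[[d]] <- if (is.null(terms)) c(prevalent = 0, incident = 0) else
      c(prevalent = effective_discount(terms, "existing"),
        incident = effective_discount(terms, "new"))
  }

  # accumulate integer cents in an array [year, drug, component]
  acc <- array(0, dim = c(pop$horizon, length(drugs), length(comps)),
               dimnames = list(NULL, drugs, comps))
  coh <- pop$cohorts
  for (i in seq_len(nrow(shares))) {
    s <- shares$subgroup[i]; d <- shares$drug_id[i]
    y <- shares$year[i]; sh <- shares$share[i]
    prof <- profiles[[d]]
    rows <- which(coh$subgroup == s & coh$year == y & coh$count > 0)
    for (j in rows) {
      ty <- cohort_treatment_year(coh$cohort[j], y, coh$entry_year[j], prof)
      cc <- per_patient_annual_cost(prof, ty, relapse_unit_cost,
                                    disc[[d]][[coh$cohort[j]]])
      acc[y, d, ] <- acc[y, d, ] + as_cents(coh$count[j] * sh * unclass(cc)[comps])
    }
  }

  out <- tidyr::expand_grid(year = seq_len(pop$horizon), drug_id = drugs,
                            component = comps)
  out$value <- acc[cbind(out$year, match(out$drug_id, drugs),
                         match(out$component, comps))] / 100
  structure(out, class = c("world_expenditure", class(out)),
            horizon = pop$horizon, world = scenario$world)
}

#' Net budget impact of the new world against the reference world
#'
#' Cell-wise difference (new minus reference) per year and component,
#' aggregated over drugs; negative cells are savings.  Row totals and the
#' grand total are recomputed from the components by exact cent summation,
#' never carried over.
#'
#' @param new_world,reference_world `world_expenditure` objects sharing the
#'   same horizon.
#' @return an object of class `budget_impact_table`: a list with `impact`
#'   (wide tibble `year` x five components + `total`), `by_drug` (tidy
#'   drug-level differences), `component_totals` (named 5-vector over the
#'   horizon) and `grand_total`.
#' @export
net_budget_impact <- function(new_world, reference_world) {
  stopifnot(inherits(new_world, "world_expenditure"),
            inherits(reference_world, "world_expenditure"))
  if (attr(new_world, "horizon") != attr(reference_world, "horizon")) {
    stop("worlds have different horizons", call. = FALSE)
  }
  comps <- bia_components()
  tidy_diff <- dplyr::full_join(
    dplyr::rename(tibble::as_tibble(new_world), new = "value"),
    dplyr::rename(tibble::as_tibble(reference_world), ref = "value"),
    by = c("year", "drug_id", "component"))
  tidy_diff$new[is.na(tidy_diff$new)] <- 0
  tidy_diff$ref[is.na(tidy_diff$ref)] <- 0
  tidy_diff$value <- (as_cents(tidy_diff$new) - as_cents(tidy_diff$ref)) / 100
  by_drug <- tidy_diff[, c("year", "drug_id", "component", "value")]

  cells <- by_drug |>
    dplyr::group_by(.data$year, .data$component) |>
    dplyr::summarise(value = sum_cents(.data$value), .groups = "drop")
  impact <- tidyr::pivot_wider(cells, names_from = "component",
                               values_from = "value")
  for (cmp in setdiff(comps, names(impact))) impact[[cmp]] <- 0
  impact <- impact[, c("year", comps)]
  impact$total <- vapply(seq_len(nrow(impact)), function(i) {
    sum_cents(unlist(impact[i, comps]))
  }, numeric(1))
  component_totals <- vapply(comps, function(cmp) sum_cents(impact[[cmp]]),
                             numeric(1))
  grand_total <- sum_cents(component_totals)
  structure(list(impact = impact,
                 by_drug = by_drug,
                 component_totals = component_totals,
                 grand_total = grand_total),
            class = "budget_impact_table")
}

#' Horizon-total decomposition row of a budget impact table
#'
#' The five component impacts summed over the horizon plus the grand total —
#' the shape of one published scenario row.
#'
#' @param x a `budget_impact_table`.
#' @return named numeric: five components and `total`.
#' @export
bia_summary_row <- function(x) {
  stopifnot(inherits(x, "budget_impact_table"))
  c(x$component_totals, total = x$grand_total)
}

#' @export
print.budget_impact_table <- function(x, ...) {
  cat("Net budget impact (new world - reference world), SAR\n")
  df <- as.data.frame(x$impact)
  df[-1] <- lapply(df[-1], function(v) sprintf("%.2f", v))
  print(df, row.names = FALSE)
  cat(sprintf("Grand total over horizon: %.2f\n", x$grand_total))
  invisible(x)
}

#' Combined scenario: several new drugs split within each subgroup
#'
#' Builds the new world from per-subgroup drug splits (fractions summing to
#' 1 within each subgroup, constant over the horizon), runs it against a
#' reference scenario and returns the aggregate net budget impact.  By
#' linearity the result equals the split-weighted sum of the corresponding
#' single-drug full-uptake tables.
#'
#' @param pop a `subgroup_population`.
#' @param splits named list: subgroup -> named numeric of drug splits
#'   summing to 1.
#' @param profiles named list of [drug_cost_profile()] objects.
#' @param relapse_unit_cost SAR per relapse event.
#' @param reference a reference [market_scenario()] covering the same
#'   subgroups.
#' @param meas,mea_select MEA set and variant selector (optional).
#' @return a `budget_impact_table`.
#' @export
combined_scenario <- function(pop, splits, profiles, relapse_unit_cost,
                              reference, meas = NULL, mea_select = NULL) {
  stopifnot(inherits(pop, "subgroup_population"), is.list(splits))
  rows <- list()
  for (s in names(splits)) {
    sp <- splits[[s]]
    if (is.null(names(sp)) || abs(sum(sp) - 1) > 1e-9) {
      stop(sprintf("drug splits for subgroup '%s' must be named and sum to 1", s),
           call. = FALSE)
    }
    rows[[s]] <- tidyr::expand_grid(subgroup = s, drug_id = names(sp),
                                    year = seq_len(pop$horizon)) |>
      dplyr::mutate(share = unname(sp[.data$drug_id]))
  }
  new_sc <- market_scenario("new", dplyr::bind_rows(rows))
  pop_used <- filter_subgroups(pop, names(splits))
  new_w <- world_expenditure(pop_used, new_sc, profiles, relapse_unit_cost,
                             meas, mea_select)
  ref_w <- world_expenditure(pop_used, reference, profiles, relapse_unit_cost)
  net_budget_impact(new_w, ref_w)
}
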