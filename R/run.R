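#' Run one budget impact scenario from a bundle
#'
#' Net budget impact of introducing one intervention in one subgroup against
#' the SOC reference world, under expert market shares or 100% uptake, with
#' or without the configured MEAs.
#'
#' @param bundle a `bia_bundle` (see [generate_bundle()] / [load_config()]).
#' @param subgroup subgroup identifier.
#' @param drug intervention drug id.
#' @param uptake `"expert"` (elicited share ranges, linearly interpolated)
#'   or `"full"` (share 1 on `drug`).
#' @param mea `"none"`, or a variant selector applied to multi-variant
#'   drugs (e.g. `"mea1"`); single-terms contracts apply as configured.
#' @param pop optional precomputed `subgroup_population` (saves re-running
#'   the cascade in batch settings).
#' @return a `budget_impact_table` with a `labels` attribute.
#' @export
run_bia <- function(bundle, subgroup, drug, uptake = c("expert", "full"),
                    mea = "none", pop = NULL) {
  uptake <- match.arg(uptake)
  validate_bundle(bundle)
  if (is.null(pop)) pop <- project_population(bundle$cascade, bundle$horizon)
  pop_s <- filter_subgroups(pop, subgroup)
  if (uptake == "expert") {
    rng <- bundle$share_ranges[bundle$share_ranges$subgroup == subgroup &
                                 bundle$share_ranges$drug_id == drug, ]
    if (!nrow(rng)) {
      stop(sprintf("no expert share range configured for drug '%s' in subgroup '%s'",
                   drug, subgroup), call. = FALSE)
    }
    sh <- build_shares("expert", bundle$horizon, new_ranges = rng,
                       soc_mix = bundle$soc_mix)
  } else {
    sh <- build_shares("full", bundle$horizon, full_drug = drug)
  }
  new_sc <- market_scenario("new", subgroup_shares(subgroup, sh))
  ref_sc <- soc_reference(bundle$soc_mix, bundle$horizon, subgroup)
  meas <- if (identical(mea, "none")) NULL else bundle$meas
  sel <- if (identical(mea, "none")) NULL else mea
  new_w <- world_expenditure(pop_s, new_sc, bundle$profiles,
                             bundle$relapse_unit_cost, meas, sel)
  ref_w <- world_expenditure(pop_s, ref_sc, bundle$profiles,
                             bundle$relapse_unit_cost)
  out <- net_budget_impact(new_w, ref_w)
  attr(out, "labels") <- c(subgroup = subgroup, drug = drug,
                           uptake = uptake, mea = mea)
  out
}

#' Run one subgroup scenario over its whole new-intervention set
#'
#' Expert mode places every eligible new intervention at its elicited share
#' range simultaneously (SOC absorbing the residual); full mode puts the
#' subgroup's featured drug at share 1.
#'
#' @param bundle a `bia_bundle`.
#' @param subgroup subgroup identifier.
#' @param uptake `"expert"` or `"full"`.
#' @param mea `"none"` or a variant selector (see [run_bia()]).
#' @param featured drug taking share 1 under full uptake; defaults to the
#'   subgroup's first eligible intervention.
#' @param pop optional precomputed `subgroup_population`.
#' @return a `budget_impact_table` with a `labels` attribute.
#' @export
run_subgroup_scenario <- function(bundle, subgroup,
                                  uptake = c("expert", "full"),
                                  mea = "none", featured = NULL, pop = NULL) {
  uptake <- match.arg(uptake)
  validate_bundle(bundle)
  if (is.null(pop)) pop <- project_population(bundle$cascade, bundle$horizon)
  pop_s <- filter_subgroups(pop, subgroup)
  elig <- bundle$eligibility$drug_id[bundle$eligibility$subgroup == subgroup]
  if (!length(elig)) {
    stop(sprintf("no interventions configured for subgroup '%s'", subgroup),
         call. = FALSE)
  }
  if (uptake == "expert") {
    rng <- bundle$share_ranges[bundle$share_ranges$subgroup == subgroup, ]
    sh <- build_shares("expert", bundle$horizon, new_ranges = rng,
                       soc_mix = bundle$soc_mix)
  } else {
    if (is.null(featured)) featured <- elig[1]
    sh <- build_shares("full", bundle$horizon, full_drug = featured)
  }
  new_sc <- market_scenario("new", subgroup_shares(subgroup, sh))
  ref_sc <- soc_reference(bundle$soc_mix, bundle$horizon, subgroup)
  meas <- if (identical(mea, "none")) NULL else bundle$meas
  sel <- if (identical(mea, "none")) NULL else mea
  new_w <- world_expenditure(pop_s, new_sc, bundle$profiles,
                             bundle$relapse_unit_cost, meas, sel)
  ref_w <- world_expenditure(pop_s, ref_sc, bundle$profiles,
                             bundle$relapse_unit_cost)
  out <- net_budget_impact(new_w, ref_w)
  attr(out, "labels") <- c(subgroup = subgroup,
                           drug = if (uptake == "full") featured else "all_eligible",
                           uptake = uptake, mea = mea)
  out
}

#' Execute the scenario matrix
#'
#' Cartesian product of subgroups, uptake modes and MEA selectors.  Each
#' cell runs [run_subgroup_scenario()]; a failing cell is reported in the
#' `error` column and the matrix continues.  Identical inputs give
#' identical outputs — there is no hidden state.
#'
#' @param bundle a `bia_bundle`.
#' @param subgroups subgroups to include (default all five).
#' @param uptake_modes subset of `c("expert", "full")`.
#' @param mea_selectors vector of MEA selectors (`"none"` plus variant
#'   names; default `c("none", "mea1")`).
#' @return tibble with label columns `subgroup`, `uptake`, `mea`, an
#'   `error` column (`NA` on success), `grand_total`, and a `table`
#'   list-column of `budget_impact_table` objects.
#' @export
run_scenario_matrix <- function(bundle, subgroups = rrms_subgroups(),
                                uptake_modes = c("expert", "full"),
                                mea_selectors = c("none", "mea1")) {
  validate_bundle(bundle)
  pop <- project_population(bundle$cascade, bundle$horizon)
  cells <- tidyr::expand_grid(subgroup = subgroups, uptake = uptake_modes,
                              mea = mea_selectors)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    tryCatch(
      list(table = run_subgroup_scenario(bundle, cells$subgroup[i],
                                         cells$uptake[i], cells$mea[i],
                                         pop = pop),
           error = NA_character_),
      error = function(e) list(table = NULL, error = conditionMessage(e)))
  })
  cells$error <- vapply(res, `[[`, character(1), "error")
  cells$grand_total <- vapply(res, function(r) {
    if (is.null(r$table)) NA_real_ else r$table$grand_total
  }, numeric(1))
  cells$table <- lapply(res, `[[`, "table")
  cells
}
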