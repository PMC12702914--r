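#' Apply epidemiological parameter overrides to a cascade
#'
#' The seven one-way sensitivity parameters: MS prevalence, the RRMS
#' fraction of MS, the treatment-eligible fraction of RRMS, the three
#' severity proportions, and the treatment-naive proportion within the
#' severity subgroups (applied to both the highly-active and aggressive
#' naive splits; the active subgroup is modelled naive-only).
#'
#' @param cascade an [eligibility_cascade()].
#' @param params named numeric; any subset of `ms_prevalence`, `frac_rrms`,
#'   `frac_eligible`, `p_active`, `p_ha`, `p_agg`, `p_naive`.
#' @return a new `eligibility_cascade`.
#' @export
cascade_update <- function(cascade, params) {
  stopifnot(inherits(cascade, "eligibility_cascade"))
  known <- c("ms_prevalence", "frac_rrms", "frac_eligible",
             "p_active", "p_ha", "p_agg", "p_naive")
  bad <- setdiff(names(params), known)
  if (length(bad)) {
    stop("unknown sensitivity parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sev <- cascade$severity_split
  nai <- cascade$naive_split
  if ("p_active" %in% names(params)) sev[["active"]] <- params[["p_active"]]
  if ("p_ha" %in% names(params)) sev[["highly_active"]] <- params[["p_ha"]]
  if ("p_agg" %in% names(params)) sev[["aggressive"]] <- params[["p_agg"]]
  if ("p_naive" %in% names(params)) {
    nai[["highly_active"]] <- params[["p_naive"]]
    nai[["aggressive"]] <- params[["p_naive"]]
  }
  eligibility_cascade(
    adult_population = cascade$adult_population,
    ms_prevalence = if ("ms_prevalence" %in% names(params))
      params[["ms_prevalence"]] else cascade$ms_prevalence,
    ms_incidence = cascade$ms_incidence,
    frac_rrms = if ("frac_rrms" %in% names(params))
      params[["frac_rrms"]] else cascade$frac_rrms,
    frac_eligible = if ("frac_eligible" %in% names(params))
      params[["frac_eligible"]] else cascade$frac_eligible,
    severity_split = sev,
    naive_split = nai,
    exit_rate = cascade$exit_rate)
}

#' Default one-way sensitivity specifications
#'
#' Base values read from a cascade; bounds default to +/-20% of base, the
#' conventional deterministic-OSA default, and are per-parameter
#' configurable afterwards.  Fraction bounds are truncated to the feasible
#' region: no upper bound exceeds 1, and a severity-proportion bound never
#' pushes the severity split's sum above 1 (the perturbed cascade must stay
#' a valid cascade).
#'
#' @param cascade an [eligibility_cascade()].
#' @param rel relative half-width of the perturbation interval.
#' @return tibble `parameter`, `base`, `low`, `high`.
#' @export
sensitivity_specs <- function(cascade, rel = 0.2) {
  stopifnot(inherits(cascade, "eligibility_cascade"), rel >= 0)
  bases <- c(ms_prevalence = cascade$ms_prevalence,
             frac_rrms = cascade$frac_rrms,
             frac_eligible = cascade$frac_eligible,
             p_active = cascade$severity_split[["active"]],
             p_ha = cascade$severity_split[["highly_active"]],
             p_agg = cascade$severity_split[["aggressive"]],
             p_naive = cascade$naive_split[["highly_active"]])
  sev_slack <- max(0, 1 - sum(cascade$severity_split))
  cap <- c(ms_prevalence = Inf, frac_rrms = 1, frac_eligible = 1,
           p_active = bases[["p_active"]] + sev_slack,
           p_ha = bases[["p_ha"]] + sev_slack,
           p_agg = bases[["p_agg"]] + sev_slack,
           p_naive = 1)
  tibble::tibble(parameter = names(bases),
                 base = unname(bases),
                 low = unname(bases * (1 - rel)),
                 high = unname(pmin(bases * (1 + rel), cap[names(bases)])))
}

#' Total-cost closure for a featured-drug scenario
#'
#' Returns a function mapping a sensitivity parameter set to the 5-year
#' total expenditure (SAR) of the with-intervention world: featured drugs
#' take their per-subgroup splits in the subgroups where they are featured,
#' and every other subgroup remains on the SOC basket.  The tornado outcome
#' is this total estimated cost.
#'
#' @param bundle a `bia_bundle`.
#' @param featured named list: subgroup -> named drug splits summing to 1
#'   (a single drug at split 1 gives the full-uptake scenario).
#' @param mea `"none"` or a variant selector (see [run_bia()]).
#' @return function `(params) -> SAR total`.
#' @export
scenario_total_closure <- function(bundle, featured, mea = "none") {
  validate_bundle(bundle)
  stopifnot(is.list(featured), length(featured) >= 1)
  meas <- if (identical(mea, "none")) NULL else bundle$meas
  sel <- if (identical(mea, "none")) NULL else mea
  rest <- setdiff(rrms_subgroups(), names(featured))
  function(params) {
    casc <- cascade_update(bundle$cascade, params)
    pop <- project_population(casc, bundle$horizon)
    rows <- dplyr::bind_rows(
      lapply(names(featured), function(s) {
        sp <- featured[[s]]
        if (abs(sum(sp) - 1) > 1e-9) {
          stop(sprintf("featured splits for subgroup '%s' must sum to 1", s),
               call. = FALSE)
        }
        tidyr::expand_grid(subgroup = s, drug_id = names(sp),
                           year = seq_len(bundle$horizon)) |>
          dplyr::mutate(share = unname(sp[.data$drug_id]))
      }))
    if (length(rest)) {
      rows <- dplyr::bind_rows(rows, soc_reference(bundle$soc_mix,
                                                   bundle$horizon,
                                                   rest)$shares)
    }
    sc <- market_scenario("new", rows)
    w <- world_expenditure(pop, sc, bundle$profiles, bundle$relapse_unit_cost,
                           meas, sel)
    sum_cents(w$value)
  }
}

#' One-way (tornado) sensitivity analysis
#'
#' Perturbs each parameter to its low and high bound with all others at
#' base, records the model total at both ends, and ranks parameters by the
#' absolute swing `|total(high) - total(low)|`, descending.  Deterministic;
#' a closure failure is propagated with the offending parameter named.
#'
#' @param closure function mapping a named parameter vector to a grand-total
#'   SAR (see [scenario_total_closure()]).
#' @param specs tibble `parameter`, `base`, `low`, `high` with
#'   `low <= base <= high` (see [sensitivity_specs()]).
#' @return tibble `parameter`, `base`, `low`, `high`, `total_at_low`,
#'   `total_at_high`, `swing`, `rank`, sorted by swing descending.
#' @export
one_way_sensitivity <- function(closure, specs) {
  specs <- tibble::as_tibble(specs)
  if (!nrow(specs)) stop("specs must be non-empty", call. = FALSE)
  if (any(specs$low > specs$base | specs$base > specs$high)) {
    bad <- specs$parameter[which(specs$low > specs$base |
                                   specs$base > specs$high)[1]]
    stop(sprintf("parameter '%s': bounds must satisfy low <= base <= high", bad),
         call. = FALSE)
  }
  base <- stats::setNames(specs$base, specs$parameter)
  eval_at <- function(p, value, which) {
    pars <- base
    pars[[p]] <- value
    tryCatch(closure(pars),
             error = function(e) {
               stop(sprintf("one_way_sensitivity: parameter '%s' (%s bound): %s",
                            p, which, conditionMessage(e)), call. = FALSE)
             })
  }
  out <- specs
  out$total_at_low <- vapply(seq_len(nrow(specs)), function(i) {
    eval_at(specs$parameter[i], specs$low[i], "low")
  }, numeric(1))
  out$total_at_high <- vapply(seq_len(nrow(specs)), function(i) {
    eval_at(specs$parameter[i], specs$high[i], "high")
  }, numeric(1))
  out$swing <- abs(out$total_at_high - out$total_at_low)
  out <- out[order(-out$swing), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Tornado bar chart of a one-way sensitivity analysis
#'
#' @param entries output of [one_way_sensitivity()].
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_tornado <- function(entries) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_tornado requires the ggplot2 package", call. = FALSE)
  }
  entries$parameter <- factor(entries$parameter,
                              levels = rev(entries$parameter))
  ggplot2::ggplot(entries,
                  ggplot2::aes(y = .data$parameter,
                               xmin = pmin(.data$total_at_low, .data$total_at_high),
                               xmax = pmax(.data$total_at_low, .data$total_at_high))) +
    ggplot2::geom_linerange(linewidth = 6, colour = "steelblue") +
    ggplot2::labs(x = "5-year total cost (SAR)", y = NULL,
                  title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}
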