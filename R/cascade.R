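#' Eligibility cascade for the treated RRMS population
#'
#' A multiplicative cascade turning a national adult population into the
#' treatment-eligible RRMS population, stratified into five subgroups by
#' disease activity (active / highly active / aggressive) and treatment
#' history (naive / non-naive).  The prevalent pool opens the model in year 1;
#' incident patients flow in annually.  No exits are modelled by default
#' (static payer-perspective model); an optional annual exit rate is
#' available and defaults to 0.
#'
#' @param adult_population adult population at risk, either a single count
#'   (held constant over the horizon) or one count per model year.
#' @param ms_prevalence MS prevalence per 100,000 adults.
#' @param ms_incidence MS incidence per 100,000 adults per year.
#' @param frac_rrms fraction of MS that is RRMS.
#' @param frac_eligible fraction of RRMS eligible for DMT treatment.
#' @param severity_split named fractions for `active`, `highly_active` and
#'   `aggressive` disease; may sum to less than 1 (remainder not modelled).
#' @param naive_split named fractions of treatment-naive patients per
#'   severity (remainder is non-naive).  The active subgroup is modelled
#'   naive-only, so its non-naive remainder is dropped.
#' @param exit_rate annual fraction leaving the treated pool (default 0).
#' @return an object of class `eligibility_cascade`.
#' @export
eligibility_cascade <- function(adult_population,
                                ms_prevalence,
                                ms_incidence,
                                frac_rrms,
                                frac_eligible,
                                severity_split = c(active = 0.55,
                                                   highly_active = 0.25,
                                                   aggressive = 0.08),
                                naive_split = c(active = 1,
                                                highly_active = 0.5,
                                                aggressive = 0.5),
                                exit_rate = 0) {
  check_nonneg(adult_population, "adult_population")
  check_nonneg(ms_prevalence, "ms_prevalence")
  check_nonneg(ms_incidence, "ms_incidence")
  check_fraction(frac_rrms, "frac_rrms")
  check_fraction(frac_eligible, "frac_eligible")
  check_fraction(exit_rate, "exit_rate")
  sev_names <- c("active", "highly_active", "aggressive")
  if (!all(sev_names %in% names(severity_split))) {
    stop("invalid value for 'severity_split': must name active, highly_active, aggressive",
         call. = FALSE)
  }
  severity_split <- severity_split[sev_names]
  check_fraction(severity_split, "severity_split")
  if (sum(severity_split) > 1 + 1e-9) {
    stop("invalid value for 'severity_split': fractions sum to more than 1",
         call. = FALSE)
  }
  if (!all(sev_names %in% names(naive_split))) {
    stop("invalid value for 'naive_split': must name active, highly_active, aggressive",
         call. = FALSE)
  }
  naive_split <- naive_split[sev_names]
  check_fraction(naive_split, "naive_split")
  structure(
    list(adult_population = as.numeric(adult_population),
         ms_prevalence = ms_prevalence,
         ms_incidence = ms_incidence,
         frac_rrms = frac_rrms,
         frac_eligible = frac_eligible,
         severity_split = severity_split,
         naive_split = naive_split,
         exit_rate = exit_rate),
    class = "eligibility_cascade"
  )
}

# internal: downstream multiplicative factor per subgroup (everything after
# the prevalence/incidence rate)
subgroup_factors <- function(cascade) {
  sev <- cascade$severity_split
  nai <- cascade$naive_split
  base <- cascade$frac_rrms * cascade$frac_eligible
  c(active_naive = base * sev[["active"]] * nai[["active"]],
    ha_naive     = base * sev[["highly_active"]] * nai[["highly_active"]],
    ha_nonnaive  = base * sev[["highly_active"]] * (1 - nai[["highly_active"]]),
    agg_naive    = base * sev[["aggressive"]] * nai[["aggressive"]],
    agg_nonnaive = base * sev[["aggressive"]] * (1 - nai[["aggressive"]]))
}

#' Project the eligible treated population per subgroup and model year
#'
#' Year-1 counts come from the prevalent pool
#' (`adult_population * prevalence/1e5 * downstream fractions`); each later
#' year adds the incident inflow
#' (`adult_population(t) * incidence/1e5 * downstream fractions`) on top of
#' the carried-over count.  Counts are kept as reals; rounding to whole
#' persons happens only at reporting.  The per-cohort decomposition
#' (prevalent stock vs each incident entry cohort) is retained so that drug
#' dosing schedules can be aligned to treatment years downstream.
#'
#' @param cascade an [eligibility_cascade()].
#' @param horizon number of model years (>= 1).
#' @return an object of class `subgroup_population`: a list with `counts`
#'   (tibble `subgroup`, `year`, `count`) and `cohorts` (tibble `subgroup`,
#'   `cohort` in `prevalent`/`incident`, `entry_year`, `year`, `count`).
#' @export
project_population <- function(cascade, horizon) {
  stopifnot(inherits(cascade, "eligibility_cascade"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 1) {
    stop("invalid value for 'horizon': must be >= 1", call. = FALSE)
  }
  horizon <- as.integer(horizon)
  pop <- cascade$adult_population
  if (length(pop) == 1L) pop <- rep(pop, horizon)
  if (length(pop) != horizon) {
    stop("invalid value for 'adult_population': length must be 1 or the horizon",
         call. = FALSE)
  }
  fac <- subgroup_factors(cascade)
  keep <- 1 - cascade$exit_rate

  rows <- list()
  for (s in names(fac)) {
    prev0 <- pop[1] * cascade$ms_prevalence / 1e5 * fac[[s]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      subgroup = s, cohort = "prevalent", entry_year = 1L,
      year = seq_len(horizon),
      count = prev0 * keep^(seq_len(horizon) - 1L))
    if (horizon > 1L) {
      for (t0 in 2:horizon) {
        inflow <- pop[t0] * cascade$ms_incidence / 1e5 * fac[[s]]
        yrs <- t0:horizon
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subgroup = s, cohort = "incident", entry_year = t0,
          year = yrs, count = inflow * keep^(yrs - t0))
      }
    }
  }
  cohorts <- dplyr::bind_rows(rows)
  counts <- cohorts |>
    dplyr::group_by(.data$subgroup, .data$year) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(match(.data$subgroup, rrms_subgroups()), .data$year)
  structure(list(counts = counts, cohorts = cohorts, horizon = horizon),
            class = "subgroup_population")
}

#' Restrict a projected population to selected subgroups
#'
#' @param pop a `subgroup_population`.
#' @param subgroups character vector of subgroup identifiers to keep.
#' @return a `subgroup_population` containing only the requested subgroups.
#' @export
filter_subgroups <- function(pop, subgroups) {
  stopifnot(inherits(pop, "subgroup_population"))
  bad <- setdiff(subgroups, unique(pop$counts$subgroup))
  if (length(bad)) {
    stop("unknown subgroup(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(
    counts = dplyr::filter(pop$counts, .data$subgroup %in% subgroups),
    cohorts = dplyr::filter(pop$cohorts, .data$subgroup %in% subgroups),
    horizon = pop$horizon
  ), class = "subgroup_population")
}

#' @export
print.subgroup_population <- function(x, ...) {
  cat("Projected eligible RRMS population (", x$horizon, " years)\n", sep = "")
  wide <- tidyr::pivot_wider(x$counts, names_from = "year",
                             values_from = "count", names_prefix = "y")
  wide[-1] <- lapply(wide[-1], round)
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

#' Write a population projection as tidy CSV
#'
#' Columns `subgroup`, `year`, `count`; counts rounded to whole persons at
#' reporting only.
#'
#' @param pop a `subgroup_population`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_population_csv <- function(pop, path) {
  stopifnot(inherits(pop, "subgroup_population"))
  out <- pop$counts
  out$count <- round(out$count)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
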