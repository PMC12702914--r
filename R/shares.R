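#' Build per-year market shares for one subgroup
#'
#' Two uptake modes, matching the study design:
#'
#' * `expert` — each new intervention's share moves linearly from its
#'   elicited year-1 (`low`) to year-H (`high`) value; the residual share in
#'   each year is allocated to the standard-of-care (SOC) basket in the
#'   proportions of `soc_mix`.  If the interpolated new-drug shares already
#'   exceed 1 in any year this is an error — it is never hidden by
#'   renormalisation.
#' * `full` — the entire subgroup is treated with a single named drug
#'   (share 1 in every year).
#'
#' @param mode `"expert"` or `"full"`.
#' @param horizon number of model years.
#' @param new_ranges for `expert` mode: data frame with columns `drug_id`,
#'   `low`, `high` (fractions, `low <= high` not required but both in
#'   `[0, 1]`).
#' @param full_drug for `full` mode: the single drug taking share 1.
#' @param soc_mix named fractions over SOC drugs, summing to 1; required in
#'   expert mode whenever a residual share remains.
#' @return tibble with columns `drug_id`, `year`, `share`; shares sum to 1
#'   in every year.
#' @export
build_shares <- function(mode = c("expert", "full"), horizon,
                         new_ranges = NULL, full_drug = NULL, soc_mix = NULL) {
  mode <- match.arg(mode)
  stopifnot(horizon >= 1)
  horizon <- as.integer(horizon)
  years <- seq_len(horizon)
  if (mode == "full") {
    if (is.null(full_drug) || length(full_drug) != 1L) {
      stop("full uptake requires exactly one drug", call. = FALSE)
    }
    return(tibble::tibble(drug_id = full_drug, year = years, share = 1))
  }
  new_ranges <- as.data.frame(new_ranges)
  if (!all(c("drug_id", "low", "high") %in% names(new_ranges))) {
    stop("new_ranges needs columns drug_id, low, high", call. = FALSE)
  }
  check_fraction(new_ranges$low, "new_ranges.low")
  check_fraction(new_ranges$high, "new_ranges.high")
  interp <- function(lo, hi) {
    if (horizon == 1L) return(lo)
    lo + (hi - lo) * (years - 1) / (horizon - 1)
  }
  new_shares <- do.call(rbind, lapply(seq_len(nrow(new_ranges)), function(i) {
    data.frame(drug_id = new_ranges$drug_id[i], year = years,
               share = interp(new_ranges$low[i], new_ranges$high[i]))
  }))
  per_year <- tapply(new_shares$share, new_shares$year, sum)
  if (any(per_year > 1 + 1e-9)) {
    bad <- names(per_year)[which(per_year > 1 + 1e-9)[1]]
    stop(sprintf("interpolated new-drug shares exceed 1 in year %s (sum %.4f)",
                 bad, per_year[[bad]]), call. = FALSE)
  }
  residual <- 1 - as.numeric(per_year)
  if (any(residual > 1e-9)) {
    if (is.null(soc_mix) || is.null(names(soc_mix))) {
      stop("a named soc_mix is required to absorb the residual market share",
           call. = FALSE)
    }
    check_fraction(soc_mix, "soc_mix")
    if (abs(sum(soc_mix) - 1) > 1e-9) {
      stop("soc_mix fractions must sum to 1", call. = FALSE)
    }
    soc <- do.call(rbind, lapply(names(soc_mix), function(d) {
      data.frame(drug_id = d, year = years, share = residual * soc_mix[[d]])
    }))
    new_shares <- rbind(new_shares, soc)
  }
  out <- tibble::as_tibble(new_shares[new_shares$share > 0, , drop = FALSE])
  out[order(out$year, out$drug_id), ]
}

#' A market scenario across subgroups
#'
#' Shares per (subgroup, drug, year), validated to sum to 1 in every
#' subgroup-year.
#'
#' @param world `"reference"` or `"new"`.
#' @param shares tibble with columns `subgroup`, `drug_id`, `year`, `share`.
#' @return an object of class `market_scenario`.
#' @export
market_scenario <- function(world = c("reference", "new"), shares) {
  world <- match.arg(world)
  shares <- tibble::as_tibble(shares)
  if (!all(c("subgroup", "drug_id", "year", "share") %in% names(shares))) {
    stop("shares needs columns subgroup, drug_id, year, share", call. = FALSE)
  }
  check_fraction(shares$share, "share")
  sums <- shares |>
    dplyr::group_by(.data$subgroup, .data$year) |>
    dplyr::summarise(s = sum(.data$share), .groups = "drop")
  bad <- sums[abs(sums$s - 1) > 1e-9, ]
  if (nrow(bad)) {
    stop(sprintf("market shares for subgroup '%s', year %d sum to %.6f (must be 1)",
                 bad$subgroup[1], bad$year[1], bad$s[1]), call. = FALSE)
  }
  structure(list(world = world, shares = shares), class = "market_scenario")
}

#' SOC-only reference scenario
#'
#' The reference world: every subgroup fully on the standard-of-care basket
#' in the configured internal mix, constant over the horizon.
#'
#' @param soc_mix named fractions over SOC drugs, summing to 1.
#' @param horizon number of model years.
#' @param subgroups subgroups to cover (default all five).
#' @return a `market_scenario` with `world = "reference"`.
#' @export
soc_reference <- function(soc_mix, horizon, subgroups = rrms_subgroups()) {
  check_fraction(soc_mix, "soc_mix")
  if (abs(sum(soc_mix) - 1) > 1e-9) {
    stop("soc_mix fractions must sum to 1", call. = FALSE)
  }
  shares <- tidyr::expand_grid(subgroup = subgroups,
                               drug_id = names(soc_mix),
                               year = seq_len(as.integer(horizon)))
  shares$share <- unname(soc_mix[shares$drug_id])
  market_scenario("reference", shares)
}

#' Attach one subgroup's shares into a scenario shares table
#'
#' Convenience for assembling a multi-subgroup scenario from per-subgroup
#' [build_shares()] output.
#'
#' @param subgroup subgroup identifier.
#' @param shares output of [build_shares()].
#' @return tibble with the subgroup column prepended.
#' @export
subgroup_shares <- function(subgroup, shares) {
  tibble::tibble(subgroup = subgroup, drug_id = shares$drug_id,
                 year = shares$year, share = shares$share)
}
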