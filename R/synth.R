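#' Configuration for the synthetic input generator
#'
#' The generator emulates the *structure* of the confidential national
#' inputs the model was designed for: a national adult population with MS
#' prevalence and incidence, the five-subgroup eligibility cascade, per-drug
#' per-treatment-year component costs, MEA terms (including one fixed-course
#' drug and one drug with three contract variants), elicited market-share
#' ranges, and a standard-of-care basket.  All randomness flows from `seed`.
#'
#' @param seed integer seed fixing all randomness.
#' @param n_drugs number of new interventions (2..7); the fixed-course drug
#'   (cladribine-like) and the three-variant MEA drug (ocrelizumab-like) are
#'   always included.
#' @param horizon model years (default 5, the study horizon).
#' @param adult_population adult national population at risk.
#' @param prevalence_range MS prevalence interval, per 100,000 adults
#'   (default brackets the national figure of 41).
#' @param incidence_range MS incidence interval, per 100,000 adults per year.
#' @param cost_scale named SAR magnitudes per component around which unit
#'   costs are sampled (log-uniformly, then rounded to the cent).
#' @param discount_range interval for fixed MEA discounts.  A degenerate
#'   `c(0, 0)` produces zero-valued contracts everywhere (including the
#'   patient-split variants), so the MEA world collapses onto the no-MEA
#'   world.
#' @param soc_basket_size number of SOC comparator drugs (1..7).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_drugs = 7L,
                         horizon = 5L,
                         adult_population = 1.5e7,
                         prevalence_range = c(35, 50),
                         incidence_range = c(3, 8),
                         cost_scale = c(acquisition = 60000,
                                        administration = 3000,
                                        monitoring = 2500,
                                        premedication = 400,
                                        adverse_events = 1500,
                                        relapse_unit = 12000),
                         discount_range = c(0.1, 0.5),
                         soc_basket_size = 4L) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  n_drugs <- as.integer(n_drugs)
  horizon <- as.integer(horizon)
  soc_basket_size <- as.integer(soc_basket_size)
  if (n_drugs < 2L || n_drugs > 7L) stop("n_drugs must be in 2..7", call. = FALSE)
  if (horizon < 1L) stop("horizon must be >= 1", call. = FALSE)
  if (soc_basket_size < 1L || soc_basket_size > 7L) {
    stop("soc_basket_size must be in 1..7", call. = FALSE)
  }
  ck_range <- function(x, field, lo = 0) {
    if (length(x) != 2L || anyNA(x) || x[1] > x[2] || x[1] < lo) {
      stop(sprintf("invalid value for '%s': must be an ordered interval", field),
           call. = FALSE)
    }
  }
  ck_range(prevalence_range, "prevalence_range")
  ck_range(incidence_range, "incidence_range")
  ck_range(discount_range, "discount_range")
  check_fraction(discount_range, "discount_range")
  check_nonneg(adult_population, "adult_population")
  check_nonneg(cost_scale, "cost_scale")
  structure(list(seed = as.integer(seed), n_drugs = n_drugs, horizon = horizon,
                 adult_population = adult_population,
                 prevalence_range = prevalence_range,
                 incidence_range = incidence_range,
                 cost_scale = cost_scale,
                 discount_range = discount_range,
                 soc_basket_size = soc_basket_size),
            class = "synth_config")
}

# canonical drug rosters; ordered so the structurally required drugs survive
# any n_drugs truncation
new_dmt_roster <- function() {
  c("cladribine", "ocrelizumab", "ofatumumab", "natalizumab",
    "siponimod", "ozanimod", "peginterferon_beta_1a")
}

soc_roster <- function() {
  c("interferon_beta_1a", "interferon_beta_1b", "glatiramer_acetate",
    "dimethyl_fumarate", "teriflunomide", "fingolimod", "rituximab")
}

# drug-to-subgroup eligibility, mirroring the published intervention matrix
eligibility_matrix <- function(drugs) {
  full <- list(
    active_naive = c("peginterferon_beta_1a", "siponimod", "ozanimod",
                     "ofatumumab", "natalizumab", "ocrelizumab"),
    ha_naive = c("cladribine", "natalizumab", "ofatumumab", "ocrelizumab"),
    ha_nonnaive = c("cladribine", "natalizumab", "ofatumumab", "ocrelizumab"),
    agg_naive = c("natalizumab", "ofatumumab", "ocrelizumab"),
    agg_nonnaive = c("natalizumab", "ofatumumab", "ocrelizumab"))
  dplyr::bind_rows(lapply(names(full), function(s) {
    tibble::tibble(subgroup = s, drug_id = intersect(full[[s]], drugs))
  }))
}

# Table-4-style ocrelizumab MEA variant templates (free-goods cycle splits
# for existing patients; payer:sponsor intake splits for new patients)
mea_variant_templates <- function(zero = FALSE) {
  grp <- function(p, paid, free) {
    data.frame(patients = p, paid_units = paid,
               free_units = if (zero) 0 * free else free)
  }
  sp <- function(payer, sponsor) if (zero) 0 else sponsor
  list(
    mea1 = mea_terms("patient_split",
                     existing_groups = grp(c(100, 300), c(2, 3), c(2, 1)),
                     new_payer_patients = 50, new_sponsor_patients = sp(50, 40)),
    mea2 = mea_terms("patient_split",
                     existing_groups = grp(c(100, 300), c(2, 3), c(2, 1)),
                     new_payer_patients = 70, new_sponsor_patients = sp(70, 60)),
    mea3 = mea_terms("patient_split",
                     existing_groups = grp(400, 3, 1),
                     new_payer_patients = 100, new_sponsor_patients = sp(100, 120))
  )
}

#' Generate a complete, internally consistent model input bundle
#'
#' Deterministic per seed.  The bundle always contains a cladribine-like
#' fixed-course drug (no acquisition beyond its two dosing years), an
#' ocrelizumab-like drug with three MEA variants, and an SOC basket whose
#' drugs carry higher relapse rates than the new interventions (so relapse
#' savings appear with the expected sign).  Unit costs are sampled
#' log-uniformly around `cost_scale` and rounded to the cent; fractions are
#' rounded to a fixed number of decimals so configuration files round-trip
#' exactly.
#'
#' @param cfg a [synth_config()].
#' @return an object of class `bia_bundle`: a list with `cascade`,
#'   `horizon`, `profiles`, `soc_mix`, `share_ranges`, `eligibility`,
#'   `meas`, `relapse_unit_cost` and the generating `config`.
#' @export
generate_bundle <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_local_seed(cfg$seed, {
    H <- cfg$horizon
    lunif <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
    runif1 <- function(lo, hi) stats::runif(1, lo, hi)
    sc <- cfg$cost_scale

    cascade <- eligibility_cascade(
      adult_population = cfg$adult_population,
      ms_prevalence = round(runif1(cfg$prevalence_range[1], cfg$prevalence_range[2]), 2),
      ms_incidence = round(runif1(cfg$incidence_range[1], cfg$incidence_range[2]), 2),
      frac_rrms = 0.8,
      frac_eligible = round(runif1(0.7, 0.95), 4),
      severity_split = c(active = round(runif1(0.45, 0.60), 4),
                         highly_active = round(runif1(0.20, 0.28), 4),
                         aggressive = round(runif1(0.05, 0.10), 4)),
      naive_split = c(active = 1,
                      highly_active = round(runif1(0.4, 0.7), 4),
                      aggressive = round(runif1(0.4, 0.7), 4)))

    new_drugs <- new_dmt_roster()[seq_len(cfg$n_drugs)]
    soc_drugs <- soc_roster()[seq_len(cfg$soc_basket_size)]

    make_profile <- function(d, soc) {
      acq_scale <- if (soc) 0.4 * sc[["acquisition"]] else sc[["acquisition"]]
      maint <- round(acq_scale * lunif(0.5, 1.5), 2)
      if (!soc && d == "cladribine") {
        course <- pmin(2L, H)
        acq <- c(round(maint * c(1.2, 1)[seq_len(course)], 2), rep(0, H - course))
        fc <- course
      } else {
        acq <- if (H == 1L) maint else
          c(round(maint * runif1(1.1, 1.4), 2), rep(maint, H - 1L))
        fc <- NULL
      }
      drug_cost_profile(
        drug_id = d,
        acquisition = acq,
        administration = round(sc[["administration"]] * lunif(0.4, 1.6), 2),
        monitoring = round(sc[["monitoring"]] * lunif(0.4, 1.6), 2),
        premedication = round(sc[["premedication"]] * lunif(0.3, 1.5), 2),
        ae_cost = round(sc[["adverse_events"]] * lunif(0.4, 1.6), 2),
        arr = if (soc) round(runif1(0.35, 0.60), 3) else round(runif1(0.08, 0.30), 3),
        fixed_course_years = fc)
    }
    profiles <- c(
      stats::setNames(lapply(new_drugs, make_profile, soc = FALSE), new_drugs),
      stats::setNames(lapply(soc_drugs, make_profile, soc = TRUE), soc_drugs))

    elig <- eligibility_matrix(new_drugs)

    # expert market-share ranges per (subgroup, eligible drug); the SOC
    # basket absorbs the residual, so per-subgroup highs are kept below 0.85
    share_ranges <- elig |>
      dplyr::group_by(.data$subgroup) |>
      dplyr::group_modify(function(df, key) {
        k <- nrow(df)
        low <- stats::runif(k, 0.02, 0.12)
        high <- low + stats::runif(k, 0.02, 0.10)
        tot <- sum(high)
        if (tot > 0.85) {
          low <- low * 0.85 / tot
          high <- high * 0.85 / tot
        }
        df$low <- round(low, 4)
        df$high <- round(high, 4)
        df
      }) |>
      dplyr::ungroup()

    w <- stats::runif(length(soc_drugs))
    mix <- round(w / sum(w), 4)
    mix[length(mix)] <- round(1 - sum(mix[-length(mix)]), 4)
    soc_mix <- stats::setNames(mix, soc_drugs)

    fixed_mea_drugs <- intersect(c("cladribine", "ozanimod", "natalizumab",
                                   "ofatumumab"), new_drugs)
    mea_entries <- stats::setNames(lapply(fixed_mea_drugs, function(d) {
      mea_terms("fixed_discount",
                discount = round(runif1(cfg$discount_range[1],
                                        cfg$discount_range[2]), 4))
    }), fixed_mea_drugs)
    if ("ocrelizumab" %in% new_drugs) {
      mea_entries$ocrelizumab <-
        mea_variant_templates(zero = max(cfg$discount_range) == 0)
    }
    meas <- mea_scenario_set(mea_entries)

    bundle <- structure(
      list(cascade = cascade, horizon = H, profiles = profiles,
           soc_mix = soc_mix, share_ranges = share_ranges,
           eligibility = elig, meas = meas,
           relapse_unit_cost = round(sc[["relapse_unit"]] * lunif(0.7, 1.3), 2),
           config = cfg),
      class = "bia_bundle")
    validate_bundle(bundle)
  })
}

#' Validate a model input bundle
#'
#' Checks every cross-module invariant: cascade validity, profile schedules
#' covering the horizon, fixed-course zeros, SOC mix summing to 1, market
#' ranges being fractions with every referenced drug holding a cost profile,
#' and MEA entries referencing configured drugs.  The first violation is
#' reported with its field path.
#'
#' @param bundle a `bia_bundle`.
#' @return the bundle, invisibly-validated (returned unchanged).
#' @export
validate_bundle <- function(bundle) {
  if (!is.list(bundle) ||
      !all(c("cascade", "horizon", "profiles", "soc_mix", "share_ranges",
             "eligibility", "relapse_unit_cost") %in% names(bundle))) {
    stop("bundle: missing sections", call. = FALSE)
  }
  if (!inherits(bundle$cascade, "eligibility_cascade")) {
    stop("bundle.cascade: not an eligibility_cascade", call. = FALSE)
  }
  H <- bundle$horizon
  for (d in names(bundle$profiles)) {
    p <- bundle$profiles[[d]]
    if (!inherits(p, "drug_cost_profile")) {
      stop(sprintf("bundle.profiles.%s: not a drug_cost_profile", d), call. = FALSE)
    }
    if (length(p$acquisition) < H) {
      stop(sprintf("bundle.profiles.%s: schedule shorter than the %d-year horizon",
                   d, H), call. = FALSE)
    }
  }
  check_nonneg(bundle$relapse_unit_cost, "bundle.relapse_unit_cost")
  check_fraction(bundle$soc_mix, "bundle.soc_mix")
  if (abs(sum(bundle$soc_mix) - 1) > 1e-9) {
    stop("bundle.soc_mix: fractions must sum to 1", call. = FALSE)
  }
  if (!all(names(bundle$soc_mix) %in% names(bundle$profiles))) {
    stop("bundle.soc_mix: references a drug with no cost profile", call. = FALSE)
  }
  sr <- bundle$share_ranges
  check_fraction(sr$low, "bundle.share_ranges.low")
  check_fraction(sr$high, "bundle.share_ranges.high")
  if (!all(sr$drug_id %in% names(bundle$profiles))) {
    stop("bundle.share_ranges: references a drug with no cost profile", call. = FALSE)
  }
  if (!all(bundle$eligibility$drug_id %in% names(bundle$profiles))) {
    stop("bundle.eligibility: references a drug with no cost profile", call. = FALSE)
  }
  if (!is.null(bundle$meas)) {
    if (!inherits(bundle$meas, "mea_scenario_set")) {
      stop("bundle.meas: not an mea_scenario_set", call. = FALSE)
    }
    if (!all(names(bundle$meas) %in% names(bundle$profiles))) {
      stop("bundle.meas: references a drug with no cost profile", call. = FALSE)
    }
  }
  bundle
}
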