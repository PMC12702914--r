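#' Write a model input bundle as a structured config file
#'
#' YAML with sections `population`, `drugs`, `meas`, `scenarios`.  Currency
#' values are serialized as fixed two-decimal strings (locale-independent,
#' dot decimal separator) so files round-trip without binary-float drift;
#' fractions and rates are written as plain numbers.
#'
#' @param bundle a `bia_bundle`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  validate_bundle(bundle)
  sar <- function(x) sprintf("%.2f", x)
  casc <- bundle$cascade
  prof_block <- lapply(bundle$profiles, function(p) {
    b <- list(acquisition = sar(p$acquisition),
              administration = sar(p$administration),
              monitoring = sar(p$monitoring),
              premedication = sar(p$premedication),
              ae_cost = sar(p$ae_cost),
              arr = p$arr)
    if (!is.null(p$fixed_course_years)) b$fixed_course_years <- p$fixed_course_years
    b
  })
  terms_block <- function(t) {
    if (t$kind == "fixed_discount") {
      list(kind = "fixed_discount", discount = t$discount)
    } else {
      list(kind = "patient_split",
           existing_groups = list(patients = t$existing_groups$patients,
                                  paid_units = t$existing_groups$paid_units,
                                  free_units = t$existing_groups$free_units),
           existing_weights = t$existing_weights,
           new_payer_patients = t$new_payer_patients,
           new_sponsor_patients = t$new_sponsor_patients)
    }
  }
  mea_block <- if (is.null(bundle$meas)) NULL else {
    lapply(unclass(bundle$meas), function(e) {
      if (inherits(e, "mea_terms")) terms_block(e)
      else list(variants = lapply(e, terms_block))
    })
  }
  cfg <- list(
    population = list(
      adult_population = casc$adult_population,
      ms_prevalence = casc$ms_prevalence,
      ms_incidence = casc$ms_incidence,
      frac_rrms = casc$frac_rrms,
      frac_eligible = casc$frac_eligible,
      severity_split = as.list(casc$severity_split),
      naive_split = as.list(casc$naive_split),
      exit_rate = casc$exit_rate,
      horizon = bundle$horizon),
    drugs = list(relapse_unit_cost = sar(bundle$relapse_unit_cost),
                 profiles = prof_block),
    meas = mea_block,
    scenarios = list(
      soc_mix = as.list(bundle$soc_mix),
      eligibility = lapply(split(bundle$eligibility$drug_id,
                                 bundle$eligibility$subgroup),
                           as.list),
      share_ranges = lapply(seq_len(nrow(bundle$share_ranges)), function(i) {
        r <- bundle$share_ranges[i, ]
        list(subgroup = r$subgroup, drug_id = r$drug_id,
             low = r$low, high = r$high)
      }))
  )
  writeLines(yaml::as.yaml(cfg, precision = 12), path)
  invisible(path)
}

#' Load and validate a model input bundle from a config file
#'
#' Errors are reported in three distinct classes: a parse error (malformed
#' YAML), a schema error (missing sections/fields or structurally
#' inconsistent shares), or an invariant violation (a field value outside
#' its domain, reported with its field path by the domain constructors).
#'
#' @param path config file written by [write_bundle()] (or by hand in the
#'   same layout).
#' @return a validated `bia_bundle`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) {
                    stop("config parse error: ", conditionMessage(e),
                         call. = FALSE)
                  })
  need <- function(x, fields, where) {
    miss <- setdiff(fields, names(x))
    if (length(miss)) {
      stop(sprintf("config schema error: missing '%s' in %s",
                   miss[1], where), call. = FALSE)
    }
  }
  need(cfg, c("population", "drugs", "scenarios"), "config")
  pop <- cfg$population
  need(pop, c("adult_population", "ms_prevalence", "ms_incidence",
              "frac_rrms", "frac_eligible", "severity_split", "naive_split",
              "horizon"), "population")
  cascade <- eligibility_cascade(
    adult_population = as.numeric(unlist(pop$adult_population)),
    ms_prevalence = pop$ms_prevalence,
    ms_incidence = pop$ms_incidence,
    frac_rrms = pop$frac_rrms,
    frac_eligible = pop$frac_eligible,
    severity_split = unlist(pop$severity_split),
    naive_split = unlist(pop$naive_split),
    exit_rate = if (is.null(pop$exit_rate)) 0 else pop$exit_rate)

  need(cfg$drugs, c("relapse_unit_cost", "profiles"), "drugs")
  profiles <- lapply(names(cfg$drugs$profiles), function(d) {
    p <- cfg$drugs$profiles[[d]]
    need(p, c("acquisition", "arr"), paste0("drugs.profiles.", d))
    drug_cost_profile(
      drug_id = d,
      acquisition = as.numeric(unlist(p$acquisition)),
      administration = as.numeric(unlist(p$administration %||% 0)),
      monitoring = as.numeric(unlist(p$monitoring %||% 0)),
      premedication = as.numeric(unlist(p$premedication %||% 0)),
      ae_cost = as.numeric(p$ae_cost %||% 0),
      arr = p$arr,
      fixed_course_years = p$fixed_course_years)
  })
  names(profiles) <- names(cfg$drugs$profiles)

  parse_terms <- function(t, where) {
    need(t, "kind", where)
    if (t$kind == "fixed_discount") {
      mea_terms("fixed_discount", discount = t$discount)
    } else if (t$kind == "patient_split") {
      mea_terms("patient_split",
                existing_groups = as.data.frame(
                  lapply(t$existing_groups, function(v) as.numeric(unlist(v)))),
                existing_weights = as.numeric(unlist(t$existing_weights)),
                new_payer_patients = as.numeric(t$new_payer_patients %||% 0),
                new_sponsor_patients = as.numeric(t$new_sponsor_patients %||% 0))
    } else {
      stop(sprintf("config schema error: unknown MEA kind '%s' in %s",
                   t$kind, where), call. = FALSE)
    }
  }
  meas <- if (is.null(cfg$meas)) NULL else {
    entries <- lapply(names(cfg$meas), function(d) {
      e <- cfg$meas[[d]]
      if (!is.null(e$variants)) {
        lapply(stats::setNames(nm = names(e$variants)), function(v) {
          parse_terms(e$variants[[v]], paste0("meas.", d, ".", v))
        })
      } else parse_terms(e, paste0("meas.", d))
    })
    mea_scenario_set(stats::setNames(entries, names(cfg$meas)))
  }

  sc <- cfg$scenarios
  need(sc, c("soc_mix", "share_ranges"), "scenarios")
  soc_mix <- unlist(sc$soc_mix)
  sr <- dplyr::bind_rows(lapply(sc$share_ranges, tibble::as_tibble))
  by_sub <- split(sr$high, sr$subgroup)
  for (s in names(by_sub)) {
    if (sum(by_sub[[s]]) > 1 + 1e-9) {
      stop(sprintf("config schema error: expert share highs for subgroup '%s' sum to %.4f (exceed 1)",
                   s, sum(by_sub[[s]])), call. = FALSE)
    }
  }
  elig <- if (is.null(sc$eligibility)) {
    sr[, c("subgroup", "drug_id")]
  } else {
    dplyr::bind_rows(lapply(names(sc$eligibility), function(s) {
      tibble::tibble(subgroup = s, drug_id = unlist(sc$eligibility[[s]]))
    }))
  }
  validate_bundle(structure(
    list(cascade = cascade, horizon = as.integer(pop$horizon),
         profiles = profiles, soc_mix = soc_mix, share_ranges = sr,
         eligibility = elig, meas = meas,
         relapse_unit_cost = as.numeric(cfg$drugs$relapse_unit_cost),
         config = NULL),
    class = "bia_bundle"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write scenario results, a summary and a run manifest
#'
#' `results.csv` holds the tidy per-year decomposition of every table
#' (scenario labels, `year`, `component` including `total`, `value` as a
#' fixed two-decimal string); `summary.json` mirrors the published row
#' shape (five horizon-total components plus total per scenario);
#' `manifest.json` records the package version, seed, config checksum and
#' scenario labels.  With an empty table set only the manifest is written
#' and the returned status is `"empty"` rather than `"ok"`.
#'
#' @param tables output of [run_scenario_matrix()] (a tibble with label
#'   columns and a `table` list-column), or a single `budget_impact_table`.
#' @param out_dir output directory (created if needed).
#' @param seed the seed governing the run, recorded in the manifest.
#' @param config_path optional config file; its md5 checksum is recorded.
#' @param notes optional character vector of decision-log entries.
#' @return character vector of files written, with attribute `status`
#'   (`"ok"` or `"empty"`).
#' @export
write_results <- function(tables, out_dir, seed = NA_integer_,
                          config_path = NULL, notes = character()) {
  if (inherits(tables, "budget_impact_table")) {
    lab <- attr(tables, "labels")
    tables <- tibble::tibble(subgroup = lab[["subgroup"]] %||% NA,
                             uptake = lab[["uptake"]] %||% NA,
                             mea = lab[["mea"]] %||% NA,
                             error = NA_character_,
                             grand_total = tables$grand_total,
                             table = list(tables))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  label_cols <- setdiff(names(tables), c("error", "grand_total", "table"))
  ok <- !vapply(tables$table, is.null, logical(1))
  files <- character()

  if (any(ok)) {
    rows <- lapply(which(ok), function(i) {
      imp <- tables$table[[i]]$impact
      long <- tidyr::pivot_longer(imp, -"year", names_to = "component",
                                  values_to = "value")
      for (lc in rev(label_cols)) long[[lc]] <- tables[[lc]][i]
      long[, c(label_cols, "year", "component", "value")]
    })
    res <- dplyr::bind_rows(rows)
    csv_path <- file.path(out_dir, "results.csv")
    write_results_csv(res, csv_path)

    summ <- lapply(which(ok), function(i) {
      c(as.list(tables[i, label_cols]),
        as.list(round_cents(bia_summary_row(tables$table[[i]]))))
    })
    json_path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, csv_path, json_path)
  }

  manifest <- list(
    package = "rrmsbia",
    version = as.character(utils::packageVersion("rrmsbia")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config_checksum = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NA,
    scenarios = if (nrow(tables))
      apply(tables[, label_cols, drop = FALSE], 1, paste, collapse = "/")
    else character(),
    notes = notes)
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, man_path)
  structure(files, status = if (any(ok)) "ok" else "empty")
}

#' Write a tidy results table as CSV with two-decimal currency cells
#'
#' @param tbl tibble with a numeric `value` column (SAR).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_results_csv <- function(tbl, path) {
  tbl$value <- sprintf("%.2f", as.numeric(tbl$value))
  utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results CSV back into a tibble
#'
#' Values come back numeric, exact at two decimals; writing the same table
#' again reproduces the file byte for byte.
#'
#' @param path a `results.csv` written by [write_results()].
#' @return tibble with `value` numeric.
#' @export
read_results <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  out$value <- as.numeric(out$value)
  out
}
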