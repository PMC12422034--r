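#' Default run configuration
#'
#' Assembles the full set of knobs for \code{\link{run_pipeline}} with
#' every assumption flag explicit. National prevalence and coverage
#' defaults are synthetic placeholders of realistic magnitude; supply real
#' national parameter tables for policy use.
#'
#' @param seed integer seed for the synthetic trial.
#' @param trial a \code{\link{trial_config}}.
#' @param ... overrides for top-level config fields.
#' @return list of class \code{run_config}.
#' @export
default_run_config <- function(seed = 1L, trial = trial_config(), ...) {
  cfg <- list(
    seed = as.integer(seed),
    trial = trial,
    time_policy = time_policy(),
    double_travel_expense = TRUE,
    time_multiplier = "two",
    uplift_factors = c(1, 1.10, 1.20, 1.50),
    uplift_includes_capital = FALSE,
    run_sensitivity = TRUE,
    coverage = "current",
    # synthetic national parameters: prevalent adults per condition and
    # service coverage levels (current vs target 95/80/80)
    prevalence = list(Uganda = c(HIV = 1.4e6, HTN = 3.3e6, DM = 0.7e6),
                      Tanzania = c(HIV = 1.7e6, HTN = 5.0e6, DM = 1.9e6)),
    coverage_levels = list(current = c(HIV = 0.89, HTN = 0.20, DM = 0.30),
                           target = c(HIV = 0.95, HTN = 0.80, DM = 0.80)))
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Scalar fields override the defaults of \code{\link{default_run_config}};
#' trial generator fields go under a \code{trial:} mapping and are passed
#' to \code{\link{trial_config}}.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  trial_args <- raw$trial %||% list()
  raw$trial <- NULL
  # YAML mappings arrive as lists; the generator wants named vectors
  trial_args <- lapply(trial_args, function(x) {
    if (is.list(x) && length(x) && all(vapply(x, is.numeric, logical(1)))) {
      unlist(x)
    } else x
  })
  trial <- do.call(trial_config, trial_args)
  do.call(default_run_config,
          c(list(seed = raw$seed %||% 1L, trial = trial),
            raw[setdiff(names(raw), "seed")]))
}

# condition-sharing pool a profile's prevalence is drawn from: the HIV
# pool when HIV is present, otherwise the HTN pool, otherwise DM
prevalence_pool <- function(profile) {
  conds <- profile_conditions(profile)
  if ("HIV" %in% conds) "HIV" else if ("HTN" %in% conds) "HTN" else "DM"
}

#' Derive a national scale-up scenario from trial costs
#'
#' Mean monthly provider cost per participant and arm is the mean visit
#' cost times visits per month; each profile draws on the prevalence pool
#' of its lead condition (HIV if present, else HTN, else DM), with the
#' proportions of each pool split across its profiles according to the
#' costed sample, times the pool's coverage level.
#'
#' @param provider_costs per-visit provider costs for one country.
#' @param participants participant table for the same country.
#' @param country country name.
#' @param prevalence named numeric: prevalent counts per condition.
#' @param coverage named numeric: coverage per condition in [0, 1].
#' @param visits_per_month mean visits per participant-month.
#' @param economy an \code{\link{economy_parameters}} object (CHE/GDP).
#' @return a \code{\link{scaleup_scenario}}.
#' @export
derive_scaleup_scenario <- function(provider_costs, participants, country,
                                    prevalence, coverage,
                                    visits_per_month = 1, economy) {
  pc <- provider_costs[provider_costs$country == country, ]
  pp <- participants[participants$country == country &
                       participants$months_enrolled >= 2L, ]
  pools <- vapply(pp$profile, prevalence_pool, character(1))
  rows <- do.call(rbind, lapply(PROFILES, function(pf) {
    pool <- prevalence_pool(pf)
    in_pool <- sum(pools == pool)
    prop <- if (in_pool == 0) 0 else sum(pp$profile == pf & pools == pool) / in_pool
    mm <- vapply(c("integrated", "standard"), function(a) {
      v <- pc$total[pc$profile == pf & pc$arm == a]
      if (length(v) == 0) 0 else mean(v) * visits_per_month
    }, numeric(1))
    data.frame(profile = pf, prevalent_count = unname(prevalence[pool]),
               proportion = prop, coverage = unname(coverage[pool]),
               monthly_integrated = mm[["integrated"]],
               monthly_standard = mm[["standard"]],
               stringsAsFactors = FALSE)
  }))
  scaleup_scenario(rows, country,
                   che = economy[[country]]$che, gdp = economy[[country]]$gdp)
}

#' Run the full costing pipeline
#'
#' Simulate, cost, compare, scale up and stress-test in one call:
#' generates the synthetic trial, allocates facility ledgers top-down,
#' costs every visit (provider, patient where questionnaires exist,
#' societal), runs all arm comparisons, projects national totals and
#' budget impact per country, and executes the sensitivity analyses.
#' If \code{out_dir} is given, writes the rendered tables as CSV, a
#' machine-readable \code{metrics.json} twin and a \code{run_log.txt}
#' recording the seed and every assumption flag in force.
#'
#' @param config a \code{run_config} (see \code{\link{default_run_config}})
#'   or a path to a YAML/JSON config file.
#' @param out_dir optional output directory.
#' @return invisible list (report bundle) with the trial, cost tables,
#'   summaries, comparisons, scale-up results and sensitivity results.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  eco <- config$trial$economy
  log_lines <- c(sprintf("intecost run, seed %d, %s", config$seed,
                         format(Sys.time(), "%Y-%m-%d")),
                 sprintf("flags: double_travel_expense=%s, time_multiplier=%s, uplift_includes_capital=%s, coverage=%s",
                         config$double_travel_expense, config$time_multiplier,
                         config$uplift_includes_capital, config$coverage))

  trial <- generate_trial(config$trial, config$seed)
  rates <- allocate_all(trial$ledgers)
  prov <- provider_visit_costs(trial$visits, rates, trial$dispensing, eco)
  table1 <- summarize_provider_costs(prov)

  have_quest <- !is.null(trial$questionnaires) && nrow(trial$questionnaires) > 0
  pat <- soc <- table2 <- table3 <- share <- NULL
  if (have_quest) {
    pat <- patient_visit_costs(trial$questionnaires, trial$participants, eco,
                               policy = config$time_policy,
                               double_travel_expense = config$double_travel_expense,
                               time_multiplier = config$time_multiplier)
    soc <- societal_visit_costs(prov, pat)
    table2 <- sample_moments(pat, "total", c("country", "arm", "profile"))
    table3 <- sample_moments(soc, "societal_total",
                             c("country", "arm", "profile"))
    share <- provider_share_of_societal(soc)
  } else {
    log_lines <- c(log_lines,
                   "notice: no questionnaires; patient/societal tables omitted")
  }

  tables <- list(provider = prov)
  if (have_quest) tables <- c(tables, list(patient = pat, societal = soc))
  comparisons <- compare_all(tables)

  cov <- config$coverage_levels[[config$coverage]]
  scaleup <- lapply(names(config$prevalence), function(co) {
    sc <- derive_scaleup_scenario(prov, trial$participants, co,
                                  config$prevalence[[co]], cov,
                                  visits_per_month = config$trial$visits_per_year / 12,
                                  economy = eco)
    national_totals(sc)
  })
  names(scaleup) <- names(config$prevalence)
  table4 <- do.call(rbind, lapply(names(scaleup), function(co) {
    data.frame(country = co, scaleup[[co]]$per_profile,
               stringsAsFactors = FALSE)
  }))

  sensitivity <- NULL
  if (isTRUE(config$run_sensitivity)) {
    sensitivity <- list(
      uplift = uplift_sweep(prov, config$uplift_factors,
                            config$uplift_includes_capital))
    if (have_quest) {
      sensitivity$time_valuation <- time_valuation_variants(
        trial$questionnaires, trial$participants, eco,
        double_travel_expense = config$double_travel_expense,
        time_multiplier = config$time_multiplier)
    }
  }

  bundle <- list(config = config, trial = trial, rates = rates,
                 provider_costs = prov, patient_costs = pat,
                 societal_costs = soc,
                 table1_provider = table1, table2_patient = table2,
                 table3_societal = table3, table4_scaleup = table4,
                 provider_share = share, comparisons = comparisons,
                 scaleup = scaleup, sensitivity = sensitivity,
                 log = log_lines)
  class(bundle) <- "intecost_report"
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  invisible(bundle)
}

#' @export
print.intecost_report <- function(x, ...) {
  cat(x$log, sep = "\n")
  cat(sprintf("visits costed: %d; comparisons: %d; countries scaled: %s\n",
              nrow(x$provider_costs), nrow(x$comparisons),
              paste(names(x$scaleup), collapse = ", ")))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' CSV tables, a metrics.json containing every number appearing in the
#' rendered tables, and a human-readable run log.
#'
#' @param bundle result of \code{\link{run_pipeline}}.
#' @param out_dir output directory, created if needed.
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  wr(bundle$trial$participants, "participants.csv")
  wr(bundle$trial$dispensing, "dispensing.csv")
  wr(bundle$trial$questionnaires, "questionnaires.csv")
  wr(bundle$trial$price_list, "price_list.csv")
  wr(bundle$table1_provider, "table1_provider_costs.csv")
  wr(bundle$table2_patient, "table2_patient_costs.csv")
  wr(bundle$table3_societal, "table3_societal_costs.csv")
  wr(bundle$table4_scaleup, "table4_scale_up.csv")
  wr(bundle$comparisons, "comparisons.csv")
  metrics <- list(
    seed = bundle$config$seed,
    table1 = bundle$table1_provider,
    table2 = bundle$table2_patient,
    table3 = bundle$table3_societal,
    table4 = bundle$table4_scaleup,
    provider_share = bundle$provider_share,
    comparisons = bundle$comparisons,
    scaleup_totals = lapply(bundle$scaleup, function(s)
      c(as.list(s$totals),
        if (!is.null(s$budget_impact)) list(budget_impact = s$budget_impact))))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(bundle$log, file.path(out_dir, "run_log.txt"))
  invisible(file.path(out_dir, "metrics.json"))
}
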