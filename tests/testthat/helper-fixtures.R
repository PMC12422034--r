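# Shared fixtures: small synthetic worlds used across test files.

# a small two-country trial, default dispersions
small_config <- function(...) {
  trial_config(n_participants = 400L,
               n_facilities = c(Uganda = 4L, Tanzania = 4L),
               visits_per_year = 6, ...)
}

# identity-conversion economy: 1 local unit = 1 Int$, flat CPI, so money
# arithmetic can be checked without conversion noise
unit_economy <- function() {
  economy_parameters(list(
    Uganda = list(ppp_rate_2021 = 1,
                  cpi = c("2019" = 100, "2020" = 100, "2021" = 100),
                  monthly_consumption = money(240, "UGX", 2021)), # 1 Int$/h
    Tanzania = list(ppp_rate_2021 = 1,
                    cpi = c("2019" = 100, "2020" = 100, "2021" = 100),
                    monthly_consumption = money(240, "TZS", 2021))))
}

# single-country world with only HIV singles and HIV+HTN multimorbid,
# HTN facility rate pinned so the true multimorbid provider-cost saving
# from integrated care is exactly `true_saving` Int$ per visit
recovery_config <- function(true_saving = 18.67, n = 240L,
                            visits_per_year = 4, ...) {
  trial_config(
    n_participants = n,
    n_facilities = c(Uganda = 8L),
    country_share = c(Uganda = 1),
    multimorbid_fraction = 1,
    single_mix = c(HIV = 1, HTN = 0, DM = 0),
    multi_mix = c("HIV+HTN" = 1, "HIV+DM" = 0, "HTN+DM" = 0,
                  "HIV+HTN+DM" = 0),
    subsample_fraction = 0,
    visits_per_year = visits_per_year,
    short_fraction = 0,
    facility_cv = 0,  # no cluster-level noise: isolates the estimator
    provider_targets = data.frame(
      country = "Uganda", condition = c("HIV", "HTN"),
      mean = c(168.85, true_saving / 0.7), sd = c(45.49, 8)),
    ...)
}

# hand-built one-facility world for rule-level provider costing tests
rule_world <- function(arm, profile, med_units = 0, med_price = 1) {
  eco <- unit_economy()
  rates <- data.frame(
    facility_id = "F1",
    profile = c("HIV", "HTN", "DM"),
    personnel_per_visit = c(100, 25, 30),
    overhead_per_visit = c(40, 10, 8),
    capital_per_visit = c(10, 5, 2),
    currency = "UGX", price_year = 2021L, stringsAsFactors = FALSE)
  visits <- data.frame(participant_id = "P1", visit_id = "P1-V01",
                       facility_id = "F1", country = "Uganda",
                       arm = arm, profile = profile, stringsAsFactors = FALSE)
  disp <- if (med_units > 0) {
    data.frame(participant_id = "P1", visit_id = "P1-V01", country = "Uganda",
               item_code = "MED", item_class = "medication",
               units = med_units, unit_price = med_price,
               currency = "UGX", price_year = 2021L, stringsAsFactors = FALSE)
  } else NULL
  provider_visit_costs(visits, rates, disp, eco)
}
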