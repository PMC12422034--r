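#' Configuration for the synthetic cluster trial generator
#'
#' The generator emulates a two-country, two-arm cluster-randomised trial of
#' integrated vs vertical chronic care: facilities are randomised within
#' country, participants carry one of seven condition profiles, and every
#' cost stream (facility ledgers, dispensing, patient questionnaires) is
#' drawn from a known ground truth so downstream estimates can be checked
#' against analytic expectations.
#'
#' Provider cost targets are specified per (country, single condition) as
#' the mean and SD of the per-visit total in 2021 Int$; multimorbid
#' profiles are emergent through the care-model rules (integrated care
#' charges the shared clinic once, vertical care sums one visit per
#' condition). Defaults are anchored at the published integrated-arm
#' single-condition magnitudes.
#'
#' @param n_participants total participants across both countries.
#' @param n_facilities named integer vector of facilities per country.
#' @param country_share named numeric, participant share per country.
#' @param multimorbid_fraction fraction with two or more conditions.
#' @param single_mix,multi_mix profile mixes within the single/multimorbid
#'   strata; each sums to 1.
#' @param subsample_fraction fraction receiving the patient-cost
#'   questionnaire (first-enrolled per facility).
#' @param visits_per_year mean visits per participant-year (Poisson).
#' @param short_fraction fraction enrolled under 2 months (excluded from
#'   costing).
#' @param facility_cv between-facility coefficient of variation of
#'   facility cost rates.
#' @param diagnostic_cv,expense_cv,time_cv visit-level coefficients of
#'   variation for diagnostics, questionnaire expenses and times.
#' @param component_shares shares of the per-visit total attributed to
#'   personnel, overhead, capital, medication, diagnostic; sums to 1.
#' @param provider_targets data.frame(country, condition, mean, sd):
#'   per-visit provider cost totals, 2021 Int$.
#' @param patient_targets data.frame(country, condition, med_expense,
#'   other_medical): questionnaire expense means, 2021 Int$.
#' @param travel_targets data.frame(country, travel_expense, travel_h,
#'   facility_h): per-trip travel money and time means.
#' @param childcare_p,childcare_h probability a visit needs childcare and
#'   mean hours when it does.
#' @param family cost distribution family, \code{"gamma"} (default) or
#'   \code{"lognormal"}; both are non-negative and right-skewed.
#' @param capital_life_years,annuity_rate capital item useful life and
#'   discount rate used to build ledgers.
#' @param dispensing_price_year price year of the unit price list (the
#'   pipeline inflates it to 2021).
#' @param primary_level_share share of facilities at primary level.
#' @param degenerate if TRUE all dispersions are zeroed (every draw equals
#'   its mean) — useful for exact-value tests.
#' @param economy an \code{\link{economy_parameters}} object.
#' @return a validated list of class \code{trial_config}.
#' @export
trial_config <- function(
    n_participants = 6714L,
    n_facilities = c(Uganda = 17L, Tanzania = 15L),
    country_share = c(Uganda = 17 / 32, Tanzania = 15 / 32),
    multimorbid_fraction = 0.2362,
    single_mix = c(HIV = 0.60, HTN = 0.28, DM = 0.12),
    multi_mix = c("HIV+HTN" = 0.45, "HIV+DM" = 0.15,
                  "HTN+DM" = 0.30, "HIV+HTN+DM" = 0.10),
    subsample_fraction = 2708 / 6714,
    visits_per_year = 12,
    short_fraction = 0.03,
    facility_cv = 0.10,
    diagnostic_cv = 0.5,
    expense_cv = 0.6,
    time_cv = 0.5,
    component_shares = c(personnel = 0.50, overhead = 0.15, capital = 0.05,
                         medication = 0.25, diagnostic = 0.05),
    provider_targets = NULL,
    patient_targets = NULL,
    travel_targets = NULL,
    childcare_p = 0.15,
    childcare_h = 3,
    family = c("gamma", "lognormal"),
    capital_life_years = 5,
    annuity_rate = 0.03,
    dispensing_price_year = 2020L,
    primary_level_share = 0.6,
    degenerate = FALSE,
    economy = economy_parameters()) {

  family <- match.arg(family)
  if (is.null(provider_targets)) {
    provider_targets <- data.frame(
      country   = rep(c("Uganda", "Tanzania"), each = 3),
      condition = rep(c("HIV", "HTN", "DM"), 2),
      mean = c(168.85, 107.31, 84.17, 152.14, 27.18, 29.82),
      sd   = c(45.49, 38.13, 9.30, 56.15, 9.82, 3.60))
  }
  if (is.null(patient_targets)) {
    patient_targets <- data.frame(
      country   = rep(c("Uganda", "Tanzania"), each = 3),
      condition = rep(c("HIV", "HTN", "DM"), 2),
      med_expense   = c(2.0, 10.0, 9.0, 1.2, 8.0, 9.0),
      other_medical = c(1.0, 2.0, 2.5, 0.6, 1.5, 1.5))
  }
  if (is.null(travel_targets)) {
    travel_targets <- data.frame(
      country = c("Uganda", "Tanzania"),
      travel_expense = c(5.5, 3.2),
      travel_h = c(1.6, 1.4),
      facility_h = c(2.6, 2.4))
  }
  if (degenerate) {
    provider_targets$sd <- 0
    facility_cv <- diagnostic_cv <- expense_cv <- time_cv <- 0
    childcare_p <- 0
    short_fraction <- 0
  }

  cfg <- list(
    n_participants = as.integer(n_participants),
    n_facilities = n_facilities, country_share = country_share,
    multimorbid_fraction = multimorbid_fraction,
    single_mix = single_mix, multi_mix = multi_mix,
    subsample_fraction = subsample_fraction,
    visits_per_year = visits_per_year, short_fraction = short_fraction,
    facility_cv = facility_cv, diagnostic_cv = diagnostic_cv,
    expense_cv = expense_cv, time_cv = time_cv,
    component_shares = component_shares,
    provider_targets = provider_targets,
    patient_targets = patient_targets, travel_targets = travel_targets,
    childcare_p = childcare_p, childcare_h = childcare_h,
    family = family,
    capital_life_years = capital_life_years, annuity_rate = annuity_rate,
    dispensing_price_year = as.integer(dispensing_price_year),
    primary_level_share = primary_level_share,
    economy = economy)

  validate_trial_config(cfg)
  structure(cfg, class = "trial_config")
}

validate_trial_config <- function(cfg) {
  check_frac <- function(x, nm) {
    if (!is.numeric(x) || any(x < 0 | x > 1)) {
      stop("configuration error: ", nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$n_participants <= 0) {
    stop("configuration error: n_participants must be positive", call. = FALSE)
  }
  if (any(cfg$n_facilities < 2)) {
    stop("configuration error: n_facilities must be >= 2 per country",
         call. = FALSE)
  }
  check_frac(cfg$multimorbid_fraction, "multimorbid_fraction")
  check_frac(cfg$subsample_fraction, "subsample_fraction")
  check_frac(cfg$short_fraction, "short_fraction")
  check_frac(cfg$childcare_p, "childcare_p")
  for (nm in c("facility_cv", "diagnostic_cv", "expense_cv", "time_cv")) {
    if (cfg[[nm]] < 0) {
      stop("configuration error: ", nm, " must be non-negative (SD < 0)",
           call. = FALSE)
    }
  }
  for (nm in c("single_mix", "multi_mix", "country_share")) {
    if (abs(sum(cfg[[nm]]) - 1) > 1e-8) {
      stop("configuration error: ", nm, " must sum to 1", call. = FALSE)
    }
  }
  if (abs(sum(cfg$component_shares) - 1) > 1e-8) {
    stop("configuration error: component_shares must sum to 1", call. = FALSE)
  }
  if (any(cfg$provider_targets$sd < 0)) {
    stop("configuration error: provider_targets$sd must be non-negative (SD < 0)",
         call. = FALSE)
  }
  if (cfg$visits_per_year <= 0) {
    stop("configuration error: visits_per_year must be positive", call. = FALSE)
  }
  # component calibration must be feasible for every (country, condition)
  for (i in seq_len(nrow(cfg$provider_targets))) {
    row <- cfg$provider_targets[i, ]
    calibrate_components(row$mean, row$sd, cfg$component_shares,
                         cfg$facility_cv, cfg$diagnostic_cv)
  }
  invisible(cfg)
}

#' Split a per-visit cost total into calibrated components
#'
#' The facility share (personnel + overhead + capital) varies between
#' facilities with the given coefficient of variation, the diagnostic
#' share varies visit-to-visit with \code{diagnostic_cv}, and the
#' medication component absorbs the residual variance so the marginal
#' per-visit total has exactly the requested mean and SD.
#'
#' @param mean,sd target mean and SD of the per-visit total.
#' @param shares named shares (personnel, overhead, capital, medication,
#'   diagnostic) summing to 1.
#' @param facility_cv,diagnostic_cv dispersion parameters.
#' @return list of component means and SDs.
#' @export
calibrate_components <- function(mean, sd, shares, facility_cv, diagnostic_cv) {
  fac_mean  <- mean * sum(shares[c("personnel", "overhead", "capital")])
  fac_sd    <- facility_cv * fac_mean
  diag_mean <- mean * shares[["diagnostic"]]
  diag_sd   <- diagnostic_cv * diag_mean
  med_mean  <- mean * shares[["medication"]]
  med_var   <- sd^2 - fac_sd^2 - diag_sd^2
  if (med_var < -1e-9) {
    stop("configuration error: target sd ", sd, " is too small for ",
         "facility_cv/diagnostic_cv at mean ", mean,
         " (medication variance would be negative)", call. = FALSE)
  }
  fshare <- shares[c("personnel", "overhead", "capital")] /
    sum(shares[c("personnel", "overhead", "capital")])
  list(personnel = fac_mean * fshare[["personnel"]],
       overhead  = fac_mean * fshare[["overhead"]],
       capital   = fac_mean * fshare[["capital"]],
       facility_mean = fac_mean, facility_sd = fac_sd,
       medication_mean = med_mean, medication_sd = sqrt(max(med_var, 0)),
       diagnostic_mean = diag_mean, diagnostic_sd = diag_sd)
}

# mean/sd-parameterised non-negative draws; sd = 0 degenerates to the mean
draw_ms <- function(n, mean, sd, family = "gamma") {
  stopifnot(length(mean) %in% c(1L, n), length(sd) %in% c(1L, n))
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  out <- numeric(n)
  fixed <- sd == 0 | mean == 0
  out[fixed] <- mean[fixed]
  idx <- which(!fixed)
  if (length(idx)) {
    m <- mean[idx]; s <- sd[idx]
    if (family == "gamma") {
      shape <- (m / s)^2
      out[idx] <- stats::rgamma(length(idx), shape = shape, rate = shape / m)
    } else {
      sl <- sqrt(log(1 + (s / m)^2))
      out[idx] <- stats::rlnorm(length(idx), log(m) - sl^2 / 2, sl)
    }
  }
  out
}

# the condition clinic an integrated-care visit is billed to: the HIV
# stream when HIV is present, otherwise the costliest constituent clinic
integrated_stream <- function(profile, fac_means) {
  conds <- profile_conditions(profile)
  if ("HIV" %in% conds) return("HIV")
  conds[which.max(fac_means[conds])]
}

#' Generate a complete synthetic cluster trial
#'
#' Produces internally consistent participants, facility cost ledgers,
#' visits, dispensing records, patient questionnaires and a unit price
#' list, together with the generating ground truth. Identical
#' \code{(config, seed)} gives byte-identical output.
#'
#' Facility ledgers are built by inversion: per-visit facility rates are
#' drawn around the country targets, then monthly cost pools are set to
#' rate times monthly caseload, so top-down allocation recovers the
#' ground-truth rates exactly.
#'
#' @param config a \code{\link{trial_config}}.
#' @param seed integer seed controlling all randomness.
#' @return a list of class \code{synthetic_trial} with elements
#'   \code{participants}, \code{facilities}, \code{ledgers}, \code{visits},
#'   \code{dispensing}, \code{questionnaires}, \code{price_list},
#'   \code{ground_truth}, \code{config}, \code{seed}.
#' @export
generate_trial <- function(config = trial_config(), seed = 1L) {
  stopifnot(inherits(config, "trial_config"))
  withr::with_seed(as.integer(seed), generate_trial_impl(config, as.integer(seed)))
}

generate_trial_impl <- function(cfg, seed) {
  eco <- cfg$economy
  countries <- names(cfg$n_facilities)

  ## --- facilities: balanced randomisation to arms within country ---------
  fac <- do.call(rbind, lapply(countries, function(co) {
    nf <- cfg$n_facilities[[co]]
    arms <- sample(rep_len(c("integrated", "standard"), nf))
    data.frame(
      facility_id = sprintf("%s-F%02d", substr(co, 1, 2), seq_len(nf)),
      country = co, arm = arms,
      level = ifelse(stats::runif(nf) < cfg$primary_level_share,
                     "primary", "secondary"),
      stringsAsFactors = FALSE)
  }))

  ## --- ground-truth component calibration --------------------------------
  comp <- do.call(rbind, lapply(seq_len(nrow(cfg$provider_targets)), function(i) {
    row <- cfg$provider_targets[i, ]
    cal <- calibrate_components(row$mean, row$sd, cfg$component_shares,
                                cfg$facility_cv, cfg$diagnostic_cv)
    data.frame(country = row$country, condition = row$condition,
               total_mean = row$mean, total_sd = row$sd,
               personnel = cal$personnel, overhead = cal$overhead,
               capital = cal$capital,
               facility_mean = cal$facility_mean, facility_sd = cal$facility_sd,
               medication_mean = cal$medication_mean,
               medication_sd = cal$medication_sd,
               diagnostic_mean = cal$diagnostic_mean,
               diagnostic_sd = cal$diagnostic_sd,
               stringsAsFactors = FALSE)
  }))

  ## --- facility-level rates (Int$, then local) ---------------------------
  rate_rows <- merge(fac[, c("facility_id", "country", "arm")], comp,
                     by = "country")
  rate_rows <- rate_rows[order(rate_rows$facility_id, rate_rows$condition), ]
  mult <- draw_ms(nrow(rate_rows), 1, cfg$facility_cv, cfg$family)
  rate_rows$personnel_rate <- rate_rows$personnel * mult
  rate_rows$overhead_rate  <- rate_rows$overhead * mult
  rate_rows$capital_rate   <- rate_rows$capital * mult

  ## --- participants -------------------------------------------------------
  n_co <- round(cfg$n_participants * cfg$country_share[countries])
  n_co[length(n_co)] <- cfg$n_participants - sum(n_co[-length(n_co)])
  parts <- do.call(rbind, lapply(seq_along(countries), function(k) {
    co <- countries[k]; n <- n_co[k]
    fids <- fac$facility_id[fac$country == co]
    multi <- stats::runif(n) < cfg$multimorbid_fraction
    prof <- character(n)
    prof[!multi] <- sample(names(cfg$single_mix), sum(!multi), TRUE,
                           prob = cfg$single_mix)
    prof[multi] <- sample(names(cfg$multi_mix), sum(multi), TRUE,
                          prob = cfg$multi_mix)
    months <- rep(12L, n)
    short <- stats::runif(n) < cfg$short_fraction
    months[short] <- sample(0:1, sum(short), TRUE)
    data.frame(participant_id = sprintf("%s-P%05d", substr(co, 1, 2), seq_len(n)),
               country = co, facility_id = sample(fids, n, TRUE),
               profile = prof, months_enrolled = months,
               stringsAsFactors = FALSE)
  }))
  parts <- merge(parts, fac[, c("facility_id", "arm", "level")],
                 by = "facility_id", sort = FALSE)
  parts <- parts[order(parts$participant_id), ]
  rownames(parts) <- NULL
  # enrolment order within facility = order of participant id (ids are
  # assigned in enrolment sequence)
  parts$enrol_order <- stats::ave(seq_len(nrow(parts)), parts$facility_id,
                                  FUN = seq_along)
  # questionnaire sub-sample: first-enrolled per facility among those
  # retained long enough to be costed
  eligible <- parts$months_enrolled >= 2L
  k_fac <- tapply(eligible, parts$facility_id, function(e) {
    round(cfg$subsample_fraction * sum(e))
  })
  parts$in_questionnaire_subsample <-
    eligible & parts$enrol_order <= k_fac[parts$facility_id]

  ## --- billed stream per participant (which clinic carries the visit) ----
  fac_means <- lapply(countries, function(co) {
    stats::setNames(comp$facility_mean[comp$country == co],
                    comp$condition[comp$country == co])
  })
  names(fac_means) <- countries
  stream_of <- vapply(seq_len(nrow(parts)), function(i) {
    p <- parts$profile[i]
    if (parts$arm[i] == "integrated") {
      integrated_stream(p, fac_means[[parts$country[i]]])
    } else NA_character_  # standard care: one visit per constituent clinic
  }, character(1))
  parts$billed_stream <- stream_of

  ## --- ledgers by inversion ----------------------------------------------
  costed <- parts[parts$months_enrolled >= 2L, ]
  per_month <- cfg$visits_per_year / 12
  ledgers <- lapply(seq_len(nrow(fac)), function(i) {
    f <- fac[i, ]
    pp <- costed[costed$facility_id == f$facility_id, ]
    cnt <- stats::setNames(numeric(3), CONDITIONS)
    for (j in seq_len(nrow(pp))) {
      conds <- if (f$arm == "integrated") pp$billed_stream[j] else
        profile_conditions(pp$profile[j])
      cnt[conds] <- cnt[conds] + 1
    }
    # integer monthly caseload; ceiling keeps every active stream allocatable
    # (the ledger inversion recovers rates exactly for any positive count)
    cnt <- ceiling(cnt * per_month)
    rr <- rate_rows[rate_rows$facility_id == f$facility_id, ]
    rr <- rr[match(CONDITIONS, rr$condition), ]
    ppp <- eco[[f$country]]$ppp_rate_2021
    cur <- eco[[f$country]]$currency
    keep <- cnt > 0
    pers_pool <- sum(rr$personnel_rate[keep] * ppp * cnt[keep])
    ovh_pool  <- sum(rr$overhead_rate[keep] * ppp * cnt[keep])
    cap_month <- sum(rr$capital_rate[keep] * ppp * cnt[keep])
    af <- if (cfg$annuity_rate == 0) cfg$capital_life_years else
      (1 - (1 + cfg$annuity_rate)^(-cfg$capital_life_years)) / cfg$annuity_rate
    capital_items <- data.frame(price = cap_month * 12 * af,
                                life_years = cfg$capital_life_years)
    facility_ledger(
      facility_id = f$facility_id,
      monthly_personnel_cost = money(pers_pool, cur, 2021L),
      monthly_overhead_cost = money(ovh_pool, cur, 2021L),
      capital_items = capital_items,
      streams = data.frame(profile = CONDITIONS[keep],
                           monthly_patients = unname(cnt[keep]),
                           weight = rr$personnel_rate[keep],
                           stringsAsFactors = FALSE),
      annuity_rate = cfg$annuity_rate)
  })
  names(ledgers) <- fac$facility_id

  ## --- visits -------------------------------------------------------------
  nvis <- pmax(1L, stats::rpois(nrow(costed),
                                cfg$visits_per_year * costed$months_enrolled / 12))
  visits <- data.frame(
    participant_id = rep(costed$participant_id, nvis),
    facility_id = rep(costed$facility_id, nvis),
    country = rep(costed$country, nvis),
    arm = rep(costed$arm, nvis),
    profile = rep(costed$profile, nvis),
    stringsAsFactors = FALSE)
  visits$visit_id <- paste0(visits$participant_id, "-V",
                            sprintf("%02d", stats::ave(seq_len(nrow(visits)),
                                                       visits$participant_id,
                                                       FUN = seq_along)))

  ## --- dispensing ---------------------------------------------------------
  price_list <- default_price_list(eco, cfg$dispensing_price_year)
  cpi_fac <- vapply(countries, function(co) {
    cpi <- eco[[co]]$cpi
    unname(cpi["2021"] / cpi[as.character(cfg$dispensing_price_year)])
  }, numeric(1))
  disp <- do.call(rbind, lapply(CONDITIONS, function(cn) {
    vv <- visits[vapply(strsplit(visits$profile, "+", fixed = TRUE),
                        function(x) cn %in% x, logical(1)), ]
    if (nrow(vv) == 0L) return(NULL)
    cm <- comp[match(paste(vv$country, cn), paste(comp$country, comp$condition)), ]
    med_intd <- draw_ms(nrow(vv), cm$medication_mean, cm$medication_sd, cfg$family)
    dia_intd <- draw_ms(nrow(vv), cm$diagnostic_mean, cm$diagnostic_sd, cfg$family)
    ppp <- vapply(vv$country, function(co) eco[[co]]$ppp_rate_2021, numeric(1))
    defl <- cpi_fac[vv$country]
    med_code <- paste0("MED_", cn); dia_code <- paste0("DIAG_", cn)
    pl_key <- paste(price_list$country, price_list$item_code)
    med_price <- price_list$unit_price[match(paste(vv$country, med_code), pl_key)]
    dia_price <- price_list$unit_price[match(paste(vv$country, dia_code), pl_key)]
    rbind(
      data.frame(participant_id = vv$participant_id, visit_id = vv$visit_id,
                 country = vv$country, item_code = med_code,
                 item_class = "medication",
                 units = med_intd * ppp / defl / med_price,
                 unit_price = med_price, stringsAsFactors = FALSE),
      data.frame(participant_id = vv$participant_id, visit_id = vv$visit_id,
                 country = vv$country, item_code = dia_code,
                 item_class = "diagnostic",
                 units = dia_intd * ppp / defl / dia_price,
                 unit_price = dia_price, stringsAsFactors = FALSE))
  }))
  disp <- disp[order(disp$visit_id, disp$item_class, disp$item_code), ]
  rownames(disp) <- NULL
  disp$price_year <- cfg$dispensing_price_year
  disp$currency <- vapply(disp$country, function(co) eco[[co]]$currency,
                          character(1))

  ## --- questionnaires -----------------------------------------------------
  qp <- parts[parts$in_questionnaire_subsample, ]
  qp <- qp[order(qp$participant_id), ]
  quest <- if (nrow(qp)) {
    pt <- cfg$patient_targets
    tt <- cfg$travel_targets[match(qp$country, cfg$travel_targets$country), ]
    ppp <- vapply(qp$country, function(co) eco[[co]]$ppp_rate_2021, numeric(1))
    sum_target <- function(col) {
      vapply(seq_len(nrow(qp)), function(i) {
        conds <- profile_conditions(qp$profile[i])
        sum(pt[[col]][pt$country == qp$country[i] & pt$condition %in% conds])
      }, numeric(1))
    }
    med_t <- sum_target("med_expense"); oth_t <- sum_target("other_medical")
    n <- nrow(qp)
    childcare <- (stats::runif(n) < cfg$childcare_p) *
      draw_ms(n, cfg$childcare_h, cfg$time_cv * cfg$childcare_h, cfg$family)
    # questionnaire refers to a mid-study visit that actually happened
    nv <- tapply(visits$visit_id, visits$participant_id, length)
    visit_number <- pmin(unname(nv[qp$participant_id]), 6L)
    data.frame(
      participant_id = qp$participant_id,
      visit_id = sprintf("%s-V%02d", qp$participant_id, visit_number),
      medication_expense = draw_ms(n, med_t, cfg$expense_cv * med_t, cfg$family) * ppp,
      other_medical_expense = draw_ms(n, oth_t, cfg$expense_cv * oth_t, cfg$family) * ppp,
      travel_expense = draw_ms(n, tt$travel_expense,
                               cfg$expense_cv * tt$travel_expense, cfg$family) * ppp,
      travel_time_h = draw_ms(n, tt$travel_h, cfg$time_cv * tt$travel_h, cfg$family),
      facility_time_h = draw_ms(n, tt$facility_h, cfg$time_cv * tt$facility_h,
                                cfg$family),
      childcare_time_h = childcare,
      currency = vapply(qp$country, function(co) eco[[co]]$currency, character(1)),
      price_year = 2021L,
      stringsAsFactors = FALSE)
  } else NULL

  ## --- ground truth -------------------------------------------------------
  expected <- expected_group_means(comp, cfg)

  structure(list(
    participants = parts, facilities = fac, ledgers = ledgers,
    visits = visits, dispensing = disp, questionnaires = quest,
    price_list = price_list,
    ground_truth = list(provider_components = comp,
                        facility_rates = rate_rows,
                        patient_targets = cfg$patient_targets,
                        travel_targets = cfg$travel_targets,
                        expected = expected, seed = seed),
    config = cfg, seed = seed), class = "synthetic_trial")
}

# analytic per-(country, arm, profile) expectations of the provider cost
# per visit implied by the generating parameters and the care-model rules
expected_group_means <- function(comp, cfg) {
  out <- expand.grid(country = unique(comp$country),
                     arm = c("integrated", "standard"),
                     profile = PROFILES, stringsAsFactors = FALSE)
  out$facility_cost <- NA_real_; out$ingredients <- NA_real_
  for (i in seq_len(nrow(out))) {
    co <- out$country[i]; conds <- profile_conditions(out$profile[i])
    cm <- comp[comp$country == co, ]
    fm <- stats::setNames(cm$facility_mean, cm$condition)
    ing <- sum(cm$medication_mean[cm$condition %in% conds] +
               cm$diagnostic_mean[cm$condition %in% conds])
    fc <- if (out$arm[i] == "standard" || length(conds) == 1L) {
      if (out$arm[i] == "standard") sum(fm[conds]) else fm[conds]
    } else {
      fm[integrated_stream(out$profile[i], fm)]
    }
    out$facility_cost[i] <- fc
    out$ingredients[i] <- ing
  }
  out$total <- out$facility_cost + out$ingredients
  out
}

#' Default unit price list for dispensing items
#'
#' A synthetic price list (one medication pack and one diagnostic per
#' condition and country) in local currency at the stated price year.
#'
#' @param economy an \code{\link{economy_parameters}} object.
#' @param price_year price year of the listed prices.
#' @export
default_price_list <- function(economy, price_year = 2020L) {
  base <- data.frame(
    item_code = c("MED_HIV", "MED_HTN", "MED_DM",
                  "DIAG_HIV", "DIAG_HTN", "DIAG_DM"),
    item_class = rep(c("medication", "diagnostic"), each = 3),
    unit_intd = c(25, 0.8, 0.7, 20, 1.5, 5),
    stringsAsFactors = FALSE)
  do.call(rbind, lapply(names(economy), function(co) {
    data.frame(country = co, item_code = base$item_code,
               item_class = base$item_class,
               unit_price = base$unit_intd * economy[[co]]$ppp_rate_2021,
               currency = economy[[co]]$currency,
               price_year = as.integer(price_year),
               stringsAsFactors = FALSE)
  }))
}

#' Facility cost ledger
#'
#' Monthly personnel and overhead pools, capital items (annuitized during
#' allocation) and the condition-clinic streams the pools are spread over.
#' Stream weights carry relative resource intensity; allocation divides
#' each pool over weighted monthly caseloads.
#'
#' @param facility_id opaque id.
#' @param monthly_personnel_cost,monthly_overhead_cost \code{money}.
#' @param capital_items data.frame(price, life_years) in the same local
#'   currency as the pools.
#' @param streams data.frame(profile, monthly_patients, weight).
#' @param annuity_rate discount rate for capital annuitization.
#' @export
facility_ledger <- function(facility_id, monthly_personnel_cost,
                            monthly_overhead_cost, capital_items,
                            streams, annuity_rate = 0.03) {
  stopifnot(is_money(monthly_personnel_cost), is_money(monthly_overhead_cost))
  if (any(unclass(monthly_personnel_cost) < 0) ||
      any(unclass(monthly_overhead_cost) < 0)) {
    stop("ledger pools must be non-negative", call. = FALSE)
  }
  if (nrow(capital_items) && any(capital_items$price < 0 |
                                 capital_items$life_years <= 0)) {
    stop("capital items need price >= 0 and life_years > 0", call. = FALSE)
  }
  if (any(streams$monthly_patients < 0)) {
    stop("monthly_patients must be non-negative", call. = FALSE)
  }
  structure(list(facility_id = facility_id,
                 monthly_personnel_cost = monthly_personnel_cost,
                 monthly_overhead_cost = monthly_overhead_cost,
                 capital_items = capital_items, streams = streams,
                 annuity_rate = annuity_rate), class = "facility_ledger")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(
    "Synthetic cluster trial (seed %d): %d participants, %d facilities,\n  %d visits, %d dispensing rows, %d questionnaires\n",
    x$seed, nrow(x$participants), nrow(x$facilities), nrow(x$visits),
    nrow(x$dispensing),
    if (is.null(x$questionnaires)) 0L else nrow(x$questionnaires)))
  invisible(x)
}

#' Grouped sample moments
#'
#' Unbiased sample mean and SD (n-1 denominator) of a value column per
#' group. Groups with a single observation report \code{sd = NA}.
#'
#' @param records data.frame of records.
#' @param value name of the numeric column to summarise.
#' @param by character vector of grouping columns.
#' @return data.frame with grouping columns, \code{n}, \code{mean}, \code{sd}.
#' @export
sample_moments <- function(records, value, by) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("records must be nonempty", call. = FALSE)
  }
  key <- interaction(records[by], drop = TRUE, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(idx, function(ii) {
    v <- records[[value]][ii]
    g <- records[ii[1], by, drop = FALSE]
    g$n <- length(v); g$mean <- mean(v)
    g$sd <- if (length(v) >= 2L) stats::sd(v) else NA_real_
    g
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}
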