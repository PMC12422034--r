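#' Top-down allocation of facility cost pools to per-visit rates
#'
#' Monthly personnel and overhead pools, plus annuitized capital divided by
#' 12, are spread over the facility's condition-clinic streams in
#' proportion to weighted monthly caseload: the pool share of stream
#' \eqn{c} is \eqn{w_c n_c / \sum w n}, and its per-visit rate is that
#' share divided by \eqn{n_c}. With equal weights every visit costs the
#' same; weights encode relative resource intensity between clinics.
#'
#' @param ledger a \code{\link{facility_ledger}}.
#' @return data.frame: facility_id, profile, personnel_per_visit,
#'   overhead_per_visit, capital_per_visit, currency, price_year.
#' @export
allocate_top_down <- function(ledger) {
  stopifnot(inherits(ledger, "facility_ledger"))
  st <- ledger$streams
  total_patients <- sum(st$monthly_patients)
  pools <- c(personnel = as.numeric(ledger$monthly_personnel_cost),
             overhead = as.numeric(ledger$monthly_overhead_cost),
             capital = if (nrow(ledger$capital_items)) {
               sum(annuitize(ledger$capital_items$price, ledger$annuity_rate,
                             ledger$capital_items$life_years)) / 12
             } else 0)
  if (total_patients == 0) {
    if (sum(pools) > 0) {
      stop("allocation error: facility ", ledger$facility_id,
           " has costs but no monthly patients (rate undefined)", call. = FALSE)
    }
    return(data.frame(facility_id = character(0), profile = character(0),
                      personnel_per_visit = numeric(0),
                      overhead_per_visit = numeric(0),
                      capital_per_visit = numeric(0)))
  }
  denom <- sum(st$weight * st$monthly_patients)
  rate_of <- function(pool) pool * st$weight / denom
  data.frame(facility_id = ledger$facility_id, profile = st$profile,
             personnel_per_visit = rate_of(pools["personnel"]),
             overhead_per_visit = rate_of(pools["overhead"]),
             capital_per_visit = rate_of(pools["capital"]),
             currency = currency_of(ledger$monthly_personnel_cost),
             price_year = price_year_of(ledger$monthly_personnel_cost),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Allocate all facility ledgers
#' @param ledgers list of \code{\link{facility_ledger}} objects.
#' @return row-bound allocation table, see \code{\link{allocate_top_down}}.
#' @export
allocate_all <- function(ledgers) {
  do.call(rbind, lapply(ledgers, allocate_top_down))
}

#' Bottom-up ingredients cost of one visit's dispensing
#'
#' Class-wise sum of units times unit price over the medication and
#' diagnostic items dispensed at a visit.
#'
#' @param records data.frame with columns item_class, units, unit_price,
#'   all sharing one visit.
#' @return named numeric: \code{medication}, \code{diagnostic} (in the
#'   records' currency and price year).
#' @export
ingredients_cost <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    return(c(medication = 0, diagnostic = 0))
  }
  bad <- records$units < 0 | records$unit_price < 0
  if (any(bad)) {
    stop("data error: negative units or unit price in dispensing record(s) ",
         paste(utils::head(which(bad), 3), collapse = ", "), call. = FALSE)
  }
  amt <- records$units * records$unit_price
  c(medication = sum(amt[records$item_class == "medication"]),
    diagnostic = sum(amt[records$item_class == "diagnostic"]))
}

# facility components charged to one visit under the care-model rules:
# - integrated & multimorbid: the shared clinic is charged once (the HIV
#   stream when HIV is present, else the costliest constituent clinic);
# - standard & multimorbid: one clinic visit per condition, summed;
# - single condition: that clinic's rate in either arm.
facility_components <- function(profile, arm, facility_rates) {
  conds <- profile_conditions(profile)
  pick <- function(cc) {
    i <- match(cc, facility_rates$profile)
    if (anyNA(i)) {
      stop("allocation error: facility ", facility_rates$facility_id[1],
           " has no allocated rate for profile(s) ",
           paste(cc[is.na(i)], collapse = ", "), call. = FALSE)
    }
    i
  }
  if (arm == "standard" || length(conds) == 1L) {
    i <- pick(conds)
    c(personnel = sum(facility_rates$personnel_per_visit[i]),
      overhead = sum(facility_rates$overhead_per_visit[i]),
      capital = sum(facility_rates$capital_per_visit[i]))
  } else {
    fac_tot <- stats::setNames(
      facility_rates$personnel_per_visit + facility_rates$overhead_per_visit +
        facility_rates$capital_per_visit, facility_rates$profile)
    use <- if ("HIV" %in% conds) "HIV" else {
      present <- conds[conds %in% names(fac_tot)]
      if (length(present) == 0L) conds else
        present[which.max(fac_tot[present])]
    }
    i <- pick(use)
    c(personnel = facility_rates$personnel_per_visit[i],
      overhead = facility_rates$overhead_per_visit[i],
      capital = facility_rates$capital_per_visit[i])
  }
}

#' Provider cost of every participant-visit
#'
#' Combines top-down facility rates (personnel, overhead, annuitized
#' capital) with bottom-up ingredients costs (medication, diagnostics) for
#' each visit, applying the comorbidity rules: integrated care charges the
#' shared clinic once for multimorbid participants, vertical care sums one
#' clinic visit per condition; dispensing is summed over all conditions in
#' both arms. All components are inflated to 2021 prices and converted to
#' international dollars.
#'
#' @param visits data.frame: visit_id, participant_id, facility_id,
#'   country, arm, profile.
#' @param rates allocation table from \code{\link{allocate_all}} (local
#'   currency, 2021).
#' @param dispensing dispensing records with visit_id, item_class, units,
#'   unit_price, currency, price_year.
#' @param economy an \code{\link{economy_parameters}} object.
#' @return data.frame of per-visit provider costs in 2021 Int$ with
#'   components personnel, overhead, capital, medication, diagnostic and
#'   their total.
#' @export
provider_visit_costs <- function(visits, rates, dispensing, economy) {
  stopifnot(all(c("visit_id", "facility_id", "arm", "profile") %in% names(visits)))

  ## facility components: compute once per (facility, arm, profile) cell
  key <- unique(visits[, c("facility_id", "country", "arm", "profile")])
  comp <- t(vapply(seq_len(nrow(key)), function(i) {
    fr <- rates[rates$facility_id == key$facility_id[i], , drop = FALSE]
    facility_components(key$profile[i], key$arm[i], fr)
  }, numeric(3)))
  key$personnel <- comp[, "personnel"]
  key$overhead <- comp[, "overhead"]
  key$capital <- comp[, "capital"]
  # local 2021 -> Int$ 2021
  ppp <- vapply(key$country, function(co) economy[[co]]$ppp_rate_2021,
                numeric(1))
  for (cl in c("personnel", "overhead", "capital")) key[[cl]] <- key[[cl]] / ppp

  out <- merge(visits, key, by = c("facility_id", "country", "arm", "profile"),
               sort = FALSE)

  ## ingredients: inflate unit prices to 2021, convert, sum by visit/class
  if (!is.null(dispensing) && nrow(dispensing)) {
    d <- dispensing
    if (any(d$units < 0 | d$unit_price < 0)) {
      stop("data error: negative units or unit price in dispensing",
           call. = FALSE)
    }
    cur_map <- vapply(unique(d$currency),
                      function(cur) country_for_currency(economy, cur),
                      character(1))
    co_of <- cur_map[d$currency]
    combo <- unique(data.frame(co = co_of, yr = d$price_year,
                               stringsAsFactors = FALSE))
    combo$f <- vapply(seq_len(nrow(combo)), function(i) {
      cpi <- economy[[combo$co[i]]]$cpi
      yr <- as.character(combo$yr[i])
      if (!yr %in% names(cpi)) {
        stop("CPI index has no value for year ", yr, call. = FALSE)
      }
      unname(cpi["2021"] / cpi[yr])
    }, numeric(1))
    infl <- combo$f[match(paste(co_of, d$price_year),
                          paste(combo$co, combo$yr))]
    ppp_map <- vapply(names(economy),
                      function(co) economy[[co]]$ppp_rate_2021, numeric(1))
    ppp_d <- ppp_map[co_of]
    amount_intd <- d$units * d$unit_price * infl / ppp_d
    med <- tapply(amount_intd * (d$item_class == "medication"), d$visit_id, sum)
    dia <- tapply(amount_intd * (d$item_class == "diagnostic"), d$visit_id, sum)
    out$medication <- as.vector(med[out$visit_id])
    out$diagnostic <- as.vector(dia[out$visit_id])
    out$medication[is.na(out$medication)] <- 0
    out$diagnostic[is.na(out$diagnostic)] <- 0
  } else {
    out$medication <- 0
    out$diagnostic <- 0
  }
  out$total <- out$personnel + out$overhead + out$capital +
    out$medication + out$diagnostic
  out$currency <- "INTD"; out$price_year <- 2021L
  out[order(out$visit_id),
      c("participant_id", "visit_id", "facility_id", "country", "arm",
        "profile", "personnel", "overhead", "capital", "medication",
        "diagnostic", "total", "currency", "price_year")]
}

#' Summarise provider costs per visit by country, arm and profile
#'
#' @param visit_costs output of \code{\link{provider_visit_costs}}.
#' @param by grouping columns.
#' @return data.frame with n, mean, sd (sd reported as 0 with
#'   \code{single_obs = TRUE} when n = 1).
#' @export
summarize_provider_costs <- function(visit_costs,
                                     by = c("country", "arm", "profile")) {
  out <- sample_moments(visit_costs, "total", by)
  out$single_obs <- out$n == 1L
  out$sd[out$single_obs] <- 0
  rownames(out) <- NULL
  out
}
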