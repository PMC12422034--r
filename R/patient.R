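#' Patient and caregiver cost of each questionnaire visit
#'
#' Self-reported expenses (medication, other medical, travel) are inflated
#' to 2021 prices and converted to international dollars; reported travel,
#' facility and childcare hours are valued at the country's hourly time
#' value. For multimorbid participants receiving standard vertical care,
#' time quantities (and, by default, the travel fare) are doubled to model
#' the separate clinic visits their conditions require, and medication and
#' other-medical expenses are replaced by the integrated-arm group mean for
#' the same profile at an equivalent facility level.
#'
#' @param questionnaires questionnaire records (local currency) with
#'   participant_id, visit_id, medication_expense, other_medical_expense,
#'   travel_expense, travel_time_h, facility_time_h, childcare_time_h,
#'   currency, price_year.
#' @param participants participant table with country, arm, profile, level.
#' @param economy an \code{\link{economy_parameters}} object.
#' @param policy a \code{\link{time_policy}} used to value time.
#' @param double_travel_expense double the travel fare alongside travel
#'   time for standard-arm multimorbid participants (default TRUE: a second
#'   physical trip implies a second fare).
#' @param time_multiplier how the vertical-care composite scales time for
#'   multimorbid participants: \code{"two"} (default, the stated rule) or
#'   \code{"n_conditions"}.
#' @return data.frame of per-visit patient costs in 2021 Int$ with the six
#'   components and their total.
#' @export
patient_visit_costs <- function(questionnaires, participants, economy,
                                policy = time_policy(),
                                double_travel_expense = TRUE,
                                time_multiplier = c("two", "n_conditions")) {
  time_multiplier <- match.arg(time_multiplier)
  q <- merge(questionnaires,
             participants[, c("participant_id", "country", "arm", "profile",
                              "level")],
             by = "participant_id", sort = FALSE)
  if (nrow(q) < nrow(questionnaires)) {
    stop("join error: questionnaire participant(s) missing from the ",
         "participant table", call. = FALSE)
  }
  num_cols <- c("medication_expense", "other_medical_expense", "travel_expense",
                "travel_time_h", "facility_time_h", "childcare_time_h")
  for (cl in num_cols) {
    if (any(q[[cl]] < 0)) {
      stop("data error: negative ", cl, " in questionnaire records",
           call. = FALSE)
    }
  }

  ## hourly time value per country, as Int$ 2021
  hv <- vapply(names(economy), function(co) {
    h <- hourly_time_value(economy, co, policy)
    as.numeric(to_int_dollars(h, economy))
  }, numeric(1))

  ## expenses: local -> 2021 prices -> Int$
  cur_map <- vapply(unique(q$currency),
                    function(cur) country_for_currency(economy, cur),
                    character(1))
  co_q <- cur_map[q$currency]
  infl <- vapply(seq_len(nrow(q)), function(i) {
    cpi <- economy[[co_q[i]]]$cpi
    yr <- as.character(q$price_year[i])
    if (!yr %in% names(cpi)) stop("CPI index has no value for year ", yr,
                                  call. = FALSE)
    unname(cpi["2021"] / cpi[yr])
  }, numeric(1))
  ppp <- vapply(co_q, function(co) economy[[co]]$ppp_rate_2021, numeric(1))
  to_intd <- function(x) x * infl / ppp

  mult <- rep(1, nrow(q))
  vm <- is_multimorbid(q$profile) & q$arm == "standard"
  mult[vm] <- if (time_multiplier == "two") 2 else n_conditions(q$profile[vm])

  out <- data.frame(
    participant_id = q$participant_id, visit_id = q$visit_id,
    country = q$country, arm = q$arm, profile = q$profile, level = q$level,
    stringsAsFactors = FALSE)
  out$medication_expense <- to_intd(q$medication_expense)
  out$other_medical <- to_intd(q$other_medical_expense)
  out$travel_expense <- to_intd(q$travel_expense) *
    (if (double_travel_expense) mult else 1)
  hv_q <- hv[q$country]
  out$travel_time_cost <- q$travel_time_h * mult * hv_q
  out$facility_time_cost <- q$facility_time_h * mult * hv_q
  out$caregiver_time_cost <- q$childcare_time_h * mult * hv_q

  ## expense-equality assumption for standard care: medication and other
  ## medical expenses equal the integrated-arm mean for the same profile
  ## at an equivalent facility level
  std <- q$arm == "standard"
  if (any(std)) {
    int_rows <- out[!std, , drop = FALSE]
    for (cl in c("medication_expense", "other_medical")) {
      key_full <- paste(out$country, out$profile, out$level)
      key_part <- paste(out$country, out$profile)
      m_full <- tapply(int_rows[[cl]],
                       paste(int_rows$country, int_rows$profile, int_rows$level),
                       mean)
      m_part <- tapply(int_rows[[cl]],
                       paste(int_rows$country, int_rows$profile), mean)
      repl <- m_full[key_full[std]]
      miss <- is.na(repl)
      repl[miss] <- m_part[key_part[std][miss]]
      still <- is.na(repl)  # no integrated counterpart at all: keep own value
      repl[still] <- out[[cl]][std][still]
      if (any(still)) {
        message(sum(still), " standard-care record(s) kept self-reported ", cl,
                ": no integrated-arm counterpart cell")
      }
      out[[cl]][std] <- unname(repl)
    }
  }

  out$total <- out$medication_expense + out$other_medical +
    out$travel_expense + out$travel_time_cost + out$facility_time_cost +
    out$caregiver_time_cost
  out$currency <- "INTD"; out$price_year <- 2021L
  out
}

#' Societal cost per visit: provider plus patient
#'
#' Joins provider and patient per-visit costs on (participant, visit) and
#' sums them.
#'
#' @param provider_costs output of \code{\link{provider_visit_costs}}.
#' @param patient_costs output of \code{\link{patient_visit_costs}}.
#' @return data.frame with provider_total, patient_total, societal_total
#'   per matched visit (2021 Int$).
#' @export
societal_visit_costs <- function(provider_costs, patient_costs) {
  m <- merge(patient_costs[, c("participant_id", "visit_id", "country", "arm",
                               "profile", "total")],
             provider_costs[, c("participant_id", "visit_id", "total")],
             by = c("participant_id", "visit_id"),
             suffixes = c("_patient", "_provider"))
  if (nrow(m) < nrow(patient_costs)) {
    stop("join error: ", nrow(patient_costs) - nrow(m),
         " patient cost record(s) have no matching provider visit",
         call. = FALSE)
  }
  data.frame(participant_id = m$participant_id, visit_id = m$visit_id,
             country = m$country, arm = m$arm, profile = m$profile,
             provider_total = m$total_provider,
             patient_total = m$total_patient,
             societal_total = m$total_provider + m$total_patient,
             stringsAsFactors = FALSE)
}

#' Provider share of societal costs
#'
#' Mean (and SD) over visits of provider cost as a percentage of societal
#' cost, by country. Visits with zero societal cost are excluded with a
#' logged count.
#'
#' @param societal_costs output of \code{\link{societal_visit_costs}}.
#' @return data.frame: country, n, mean_pct, sd_pct.
#' @export
provider_share_of_societal <- function(societal_costs) {
  if (nrow(societal_costs) == 0L) stop("no societal cost records", call. = FALSE)
  zero <- societal_costs$societal_total == 0
  if (any(zero)) {
    message("excluding ", sum(zero), " visit(s) with zero societal cost")
    societal_costs <- societal_costs[!zero, , drop = FALSE]
  }
  societal_costs$share <- 100 * societal_costs$provider_total /
    societal_costs$societal_total
  out <- sample_moments(societal_costs, "share", "country")
  names(out)[names(out) %in% c("mean", "sd")] <- c("mean_pct", "sd_pct")
  out
}
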