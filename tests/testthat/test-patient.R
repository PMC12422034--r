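mk_part <- function(id, arm, profile, country = "Uganda", level = "primary") {
  data.frame(participant_id = id, country = country, arm = arm,
             profile = profile, level = level, stringsAsFactors = FALSE)
}

mk_quest <- function(id, med = 0, oth = 0, travel = 0, t_h = 0, f_h = 0,
                     c_h = 0, currency = "UGX") {
  data.frame(participant_id = id, visit_id = paste0(id, "-V01"),
             medication_expense = med, other_medical_expense = oth,
             travel_expense = travel, travel_time_h = t_h,
             facility_time_h = f_h, childcare_time_h = c_h,
             currency = currency, price_year = 2021L, stringsAsFactors = FALSE)
}

test_that("patient costs compose time valuation and PPP conversion", {
  eco <- economy_parameters() # 500 UGX/h, Int$1 = UGX 1310.6
  pc <- patient_visit_costs(mk_quest("P1", travel = 2621.2, t_h = 1, f_h = 2),
                            mk_part("P1", "integrated", "HIV"), eco)
  expect_equal(pc$total, (1 * 500 + 2 * 500 + 2621.2) / 1310.6,
               tolerance = 1e-12)
  expect_equal(pc$travel_expense, 2621.2 / 1310.6)
  # all-zero questionnaire
  pc0 <- patient_visit_costs(mk_quest("P1"),
                             mk_part("P1", "integrated", "HIV"), eco)
  expect_equal(pc0$total, 0)
})

test_that("vertical-care multimorbid time (and fare) is doubled; dispensing-derived components are not", {
  eco <- unit_economy() # 1 Int$/h, identity conversion
  parts <- rbind(mk_part("I1", "integrated", "HIV+DM"),
                 mk_part("S1", "standard", "HIV+DM"),
                 mk_part("S2", "standard", "HIV")) # single: no doubling
  q <- rbind(mk_quest("I1", med = 7, oth = 3, travel = 4, t_h = 1, f_h = 2, c_h = 1),
             mk_quest("S1", med = 7, oth = 3, travel = 4, t_h = 1, f_h = 2, c_h = 1),
             mk_quest("S2", med = 7, oth = 3, travel = 4, t_h = 1, f_h = 2, c_h = 1))
  pc <- patient_visit_costs(q, parts, eco)
  i <- pc[pc$participant_id == "I1", ]; s <- pc[pc$participant_id == "S1", ]
  expect_equal(s$travel_time_cost, 2 * i$travel_time_cost)
  expect_equal(s$facility_time_cost, 2 * i$facility_time_cost)
  expect_equal(s$caregiver_time_cost, 2 * i$caregiver_time_cost)
  expect_equal(s$travel_expense, 2 * i$travel_expense) # default fare doubling
  # expense-equality: standard med/other equal the integrated cell mean
  expect_equal(s$medication_expense, i$medication_expense)
  expect_equal(s$other_medical, i$other_medical)
  # single condition in standard care: nothing doubled
  s2 <- pc[pc$participant_id == "S2", ]
  expect_equal(s2$travel_time_cost, i$travel_time_cost)

  # fare doubling can be disabled; n_conditions multiplier is available
  pc_nf <- patient_visit_costs(q, parts, eco, double_travel_expense = FALSE)
  expect_equal(pc_nf$travel_expense[pc_nf$participant_id == "S1"],
               i$travel_expense)
  parts3 <- rbind(mk_part("I1", "integrated", "HIV+HTN+DM"),
                  mk_part("S1", "standard", "HIV+HTN+DM"))
  pc3 <- patient_visit_costs(q[1:2, ], parts3, eco,
                             time_multiplier = "n_conditions")
  expect_equal(pc3$travel_time_cost[2], 3 * pc3$travel_time_cost[1])
})

test_that("standard-arm expenses take the integrated group mean for the matching cell", {
  eco <- unit_economy()
  parts <- rbind(mk_part("I1", "integrated", "HTN", level = "primary"),
                 mk_part("I2", "integrated", "HTN", level = "primary"),
                 mk_part("S1", "standard", "HTN", level = "primary"),
                 mk_part("S2", "standard", "DM", level = "secondary"))
  q <- rbind(mk_quest("I1", med = 4), mk_quest("I2", med = 8),
             mk_quest("S1", med = 999), mk_quest("S2", med = 999))
  # S2 has no integrated DM counterpart: keeps its own value, with a notice
  expect_message(pc <- patient_visit_costs(q, parts, eco), "counterpart")
  expect_equal(pc$medication_expense[pc$participant_id == "S1"], 6) # (4+8)/2
  expect_equal(pc$medication_expense[pc$participant_id == "S2"], 999)
})

test_that("patient total is monotone in every reported hour field", {
  eco <- economy_parameters()
  set.seed(31)
  for (i in 1:20) {
    base_q <- mk_quest("P1", med = runif(1, 0, 5000), oth = runif(1, 0, 2000),
                       travel = runif(1, 0, 9000), t_h = runif(1, 0, 3),
                       f_h = runif(1, 0, 5), c_h = runif(1, 0, 4))
    part <- mk_part("P1", sample(c("integrated", "standard"), 1),
                    sample(PROFILES, 1))
    base <- patient_visit_costs(base_q, part, eco)$total
    for (cl in c("travel_time_h", "facility_time_h", "childcare_time_h")) {
      q2 <- base_q; q2[[cl]] <- q2[[cl]] + runif(1, 0, 2)
      expect_gte(patient_visit_costs(q2, part, eco)$total, base)
    }
  }
  expect_error(patient_visit_costs(mk_quest("P1", t_h = -1),
                                   mk_part("P1", "integrated", "HIV"), eco),
               "negative")
})

test_that("societal costs are the record-wise provider + patient sum", {
  cfg <- small_config()
  tr <- generate_trial(cfg, seed = 23)
  prov <- provider_visit_costs(tr$visits, allocate_all(tr$ledgers),
                               tr$dispensing, cfg$economy)
  pat <- patient_visit_costs(tr$questionnaires, tr$participants, cfg$economy)
  soc <- societal_visit_costs(prov, pat)
  expect_equal(nrow(soc), nrow(pat))
  expect_equal(soc$societal_total, soc$provider_total + soc$patient_total)
  # linearity of group means
  for (co in unique(soc$country)) {
    s <- soc[soc$country == co, ]
    expect_equal(mean(s$societal_total),
                 mean(s$provider_total) + mean(s$patient_total))
  }
  # zero patient cost: societal equals provider
  pat0 <- pat; pat0$total <- 0
  soc0 <- societal_visit_costs(prov, pat0)
  expect_equal(soc0$societal_total, soc0$provider_total)
  # key mismatch is a join error
  bad <- pat; bad$visit_id[1] <- "NO-SUCH-VISIT"
  expect_error(societal_visit_costs(prov, bad), "join error")
})

test_that("provider share of societal matches the per-record ratio oracle", {
  df <- data.frame(participant_id = "x", visit_id = "v",
                   country = c("Uganda", "Uganda", "Tanzania"),
                   arm = "integrated", profile = "HIV",
                   provider_total = c(90, 50, 0),
                   patient_total = c(10, 50, 5))
  df$societal_total <- df$provider_total + df$patient_total
  sh <- provider_share_of_societal(df)
  expect_equal(sh$mean_pct[sh$country == "Uganda"], mean(c(90, 50)))
  expect_equal(sh$mean_pct[sh$country == "Tanzania"], 0)
  # zero-societal records are excluded with a logged count
  dfz <- rbind(df, within(df[1, ], {
    provider_total <- 0; patient_total <- 0; societal_total <- 0
  }))
  expect_message(provider_share_of_societal(dfz), "zero societal")
  # brute force on synthetic records
  set.seed(7)
  big <- data.frame(participant_id = "x", visit_id = "v", country = "Uganda",
                    arm = "x", profile = "HIV",
                    provider_total = runif(50, 1, 100),
                    patient_total = runif(50, 0, 40))
  big$societal_total <- big$provider_total + big$patient_total
  expect_equal(provider_share_of_societal(big)$mean_pct,
               mean(100 * big$provider_total / big$societal_total))
})
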