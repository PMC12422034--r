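mk_ledger <- function(pers, ovh = 0, capital = NULL, streams, rate = 0.03) {
  facility_ledger(
    facility_id = "F1",
    monthly_personnel_cost = money(pers, "UGX", 2021),
    monthly_overhead_cost = money(ovh, "UGX", 2021),
    capital_items = capital %||%
      data.frame(price = numeric(0), life_years = numeric(0)),
    streams = streams, annuity_rate = rate)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("top-down allocation divides pools over weighted caseload", {
  # single stream: pool / visits
  r <- allocate_top_down(mk_ledger(10000, streams = data.frame(
    profile = "HIV", monthly_patients = 100, weight = 1)))
  expect_equal(r$personnel_per_visit, 100)

  # two equal streams of 50 visits: 9000 -> 90, 3000 -> 30 each
  r <- allocate_top_down(mk_ledger(9000, 3000, streams = data.frame(
    profile = c("HIV", "HTN"), monthly_patients = c(50, 50), weight = 1)))
  expect_equal(r$personnel_per_visit, c(90, 90))
  expect_equal(r$overhead_per_visit, c(30, 30))

  # weighted streams: proportional-share oracle
  st <- data.frame(profile = c("HIV", "HTN"), monthly_patients = c(80, 40),
                   weight = c(3, 1))
  r <- allocate_top_down(mk_ledger(2800, streams = st))
  share <- st$weight * st$monthly_patients / sum(st$weight * st$monthly_patients)
  expect_equal(r$personnel_per_visit, 2800 * share / st$monthly_patients)

  # capital composes with annuitization: 1000 at 3% over 5y, 100 visits
  r <- allocate_top_down(mk_ledger(0, 0,
    capital = data.frame(price = 1000, life_years = 5),
    streams = data.frame(profile = "HIV", monthly_patients = 100, weight = 1)))
  oracle <- (1000 / sum(1.03^-(1:5))) / 12 / 100
  expect_equal(r$capital_per_visit, oracle, tolerance = 1e-9)
  expect_equal(r$capital_per_visit, 0.182, tolerance = 1e-3)

  # zero patients with nonzero cost is undefined
  expect_error(allocate_top_down(mk_ledger(100, streams = data.frame(
    profile = "HIV", monthly_patients = 0, weight = 1)[0, ])),
    "allocation error")
})

test_that("allocation is scale-equivariant in the ledger pools", {
  st <- data.frame(profile = c("HIV", "HTN", "DM"),
                   monthly_patients = c(70, 50, 20), weight = c(2, 1, 1.5))
  base <- allocate_top_down(mk_ledger(5000, 1500,
    capital = data.frame(price = 2000, life_years = 5), streams = st))
  k <- 3.7
  scaled <- allocate_top_down(mk_ledger(5000 * k, 1500 * k,
    capital = data.frame(price = 2000 * k, life_years = 5), streams = st))
  for (cl in c("personnel_per_visit", "overhead_per_visit", "capital_per_visit")) {
    expect_equal(scaled[[cl]], k * base[[cl]], tolerance = 1e-12)
  }
})

test_that("ingredients cost sums units times price by class", {
  recs <- data.frame(item_class = c("medication", "diagnostic"),
                     units = c(60, 1), unit_price = c(0.05, 4))
  expect_equal(ingredients_cost(recs),
               c(medication = 3, diagnostic = 4))
  expect_equal(ingredients_cost(recs[0, ]), c(medication = 0, diagnostic = 0))
  expect_error(ingredients_cost(data.frame(item_class = "medication",
                                           units = -1, unit_price = 2)),
               "data error")
  # brute-force oracle on random records
  set.seed(99)
  for (i in 1:10) {
    n <- sample(1:8, 1)
    recs <- data.frame(
      item_class = sample(c("medication", "diagnostic"), n, TRUE),
      units = runif(n, 0, 100), unit_price = runif(n, 0, 50))
    got <- ingredients_cost(recs)
    brute <- c(medication = 0, diagnostic = 0)
    for (j in seq_len(n)) {
      brute[recs$item_class[j]] <- brute[recs$item_class[j]] +
        recs$units[j] * recs$unit_price[j]
    }
    expect_equal(got, brute)
  }
})

test_that("comorbidity rules: integrated charges the shared clinic once, standard sums", {
  # rates in the fixture: HIV visit 150, HTN 40, DM 40 (p+o+c)
  # integrated HIV+DM: HIV facility rate once + meds 30 -> 180
  v <- rule_world("integrated", "HIV+DM", med_units = 30, med_price = 1)
  expect_equal(v$personnel, 100)
  expect_equal(v$total, 150 + 30)
  # standard HIV+DM: HIV visit 150 + DM visit 40 + meds 30 -> 220
  v <- rule_world("standard", "HIV+DM", med_units = 30, med_price = 1)
  expect_equal(v$personnel, 130)
  expect_equal(v$total, 220)
  # single-condition visit costs the same in either arm
  for (pf in c("HIV", "HTN", "DM")) {
    vi <- rule_world("integrated", pf)
    vs <- rule_world("standard", pf)
    expect_equal(vi$total, vs$total)
  }
  # integrated multimorbid without HIV: costliest constituent clinic once
  v <- rule_world("integrated", "HTN+DM")
  expect_equal(v$total, 40) # max(HTN 40, DM 40) = 40, single charge
  vs <- rule_world("standard", "HTN+DM")
  expect_equal(vs$total, 80)
})

test_that("per-visit components are additive and satisfy dominance/equality", {
  cfg <- small_config()
  tr <- generate_trial(cfg, seed = 17)
  rates <- allocate_all(tr$ledgers)
  prov <- provider_visit_costs(tr$visits, rates, tr$dispensing, cfg$economy)
  expect_equal(prov$total,
               prov$personnel + prov$overhead + prov$capital +
                 prov$medication + prov$diagnostic, tolerance = 1e-12)
  expect_true(all(prov[c("personnel", "overhead", "capital", "medication",
                         "diagnostic")] >= 0))

  fac_cost <- prov$personnel + prov$overhead + prov$capital
  # equality: integrated multimorbid HIV-containing facility components
  # equal the facility's HIV-alone components exactly
  int_hiv_multi <- prov$arm == "integrated" & is_multimorbid(prov$profile) &
    grepl("HIV", prov$profile)
  for (f in unique(prov$facility_id[int_hiv_multi])) {
    hiv_rate <- rates[rates$facility_id == f & rates$profile == "HIV", ]
    sel <- int_hiv_multi & prov$facility_id == f
    ppp <- cfg$economy[[prov$country[sel][1]]]$ppp_rate_2021
    expect_equal(unique(prov$personnel[sel]),
                 hiv_rate$personnel_per_visit / ppp, tolerance = 1e-12)
  }
  # dominance: standard multimorbid facility cost >= costliest constituent
  std_multi <- which(prov$arm == "standard" & is_multimorbid(prov$profile))
  for (i in std_multi[seq_len(min(200, length(std_multi)))]) {
    f <- prov$facility_id[i]
    rr <- rates[rates$facility_id == f, ]
    ppp <- cfg$economy[[prov$country[i]]]$ppp_rate_2021
    constituents <- profile_conditions(prov$profile[i])
    single <- (rr$personnel_per_visit + rr$overhead_per_visit +
                 rr$capital_per_visit)[rr$profile %in% constituents] / ppp
    expect_gte(fac_cost[i] + 1e-9, max(single))
  }
})

test_that("missing rate for a required profile raises an allocation error", {
  eco <- unit_economy()
  rates <- data.frame(facility_id = "F1", profile = "HIV",
                      personnel_per_visit = 10, overhead_per_visit = 2,
                      capital_per_visit = 1, currency = "UGX",
                      price_year = 2021L)
  visits <- data.frame(participant_id = "P1", visit_id = "V1",
                       facility_id = "F1", country = "Uganda",
                       arm = "standard", profile = "HIV+DM")
  expect_error(provider_visit_costs(visits, rates, NULL, eco),
               "allocation error")
})

test_that("summaries reproduce degenerate and grouped oracle values", {
  cfg <- trial_config(
    n_participants = 60L, n_facilities = c(Tanzania = 2L),
    country_share = c(Tanzania = 1), multimorbid_fraction = 0,
    single_mix = c(HIV = 0, HTN = 1, DM = 0), subsample_fraction = 0,
    visits_per_year = 2, degenerate = TRUE,
    provider_targets = data.frame(country = "Tanzania", condition = "HTN",
                                  mean = 27.18, sd = 0))
  tr <- generate_trial(cfg, seed = 2)
  prov <- provider_visit_costs(tr$visits, allocate_all(tr$ledgers),
                               tr$dispensing, cfg$economy)
  s <- summarize_provider_costs(prov)
  expect_equal(s$mean, rep(27.18, nrow(s)), tolerance = 1e-9)
  expect_equal(s$sd, rep(0, nrow(s)), tolerance = 1e-9)

  # n = 1 group: sd reported as 0 with the single-observation flag
  one <- prov[1, ]
  s1 <- summarize_provider_costs(one)
  expect_true(s1$single_obs)
  expect_equal(s1$sd, 0)
  expect_equal(s1$mean, one$total)
})
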