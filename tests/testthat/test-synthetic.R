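test_that("identical seed and config give identical output; seeds differ", {
  cfg <- small_config()
  t1 <- generate_trial(cfg, seed = 11)
  t2 <- generate_trial(cfg, seed = 11)
  expect_identical(t1$participants, t2$participants)
  expect_identical(t1$dispensing, t2$dispensing)
  expect_identical(t1$questionnaires, t2$questionnaires)
  expect_identical(lapply(t1$ledgers, unclass), lapply(t2$ledgers, unclass))
  t3 <- generate_trial(cfg, seed = 12)
  expect_false(identical(t1$dispensing, t3$dispensing))
})

test_that("degenerate config (all SDs zero) yields exact component means", {
  cfg <- small_config(degenerate = TRUE)
  tr <- generate_trial(cfg, seed = 3)
  rates <- allocate_all(tr$ledgers)
  prov <- provider_visit_costs(tr$visits, rates, tr$dispensing, cfg$economy)
  exp <- tr$ground_truth$expected
  key <- paste(prov$country, prov$arm, prov$profile)
  want <- exp$total[match(key, paste(exp$country, exp$arm, exp$profile))]
  expect_equal(prov$total, want, tolerance = 1e-9)
  # questionnaire components equal their targets too
  q <- tr$questionnaires
  tt <- cfg$travel_targets
  expect_equal(q$travel_time_h,
               tt$travel_h[match(tr$participants$country[
                 match(q$participant_id, tr$participants$participant_id)],
                 tt$country)])
})

test_that("realised multimorbid share stays within binomial 99% bounds", {
  cfg <- trial_config() # full stated cohort, 6714 participants
  tr <- generate_trial(cfg, seed = 5)
  share <- mean(is_multimorbid(tr$participants$profile))
  p <- cfg$multimorbid_fraction
  half <- stats::qnorm(0.995) * sqrt(p * (1 - p) / nrow(tr$participants))
  expect_gt(share, p - half)
  expect_lt(share, p + half)
})

test_that("record sets are structurally consistent", {
  tr <- generate_trial(small_config(), seed = 8)
  p <- tr$participants
  # cluster randomisation: participant arm equals facility arm
  fac_arm <- setNames(tr$facilities$arm, tr$facilities$facility_id)
  expect_identical(p$arm, unname(fac_arm[p$facility_id]))
  # questionnaire participants exist and were enrolled long enough
  q <- tr$questionnaires
  expect_true(all(q$participant_id %in% p$participant_id))
  expect_true(all(p$months_enrolled[match(q$participant_id,
                                          p$participant_id)] >= 2))
  # every dispensing row references an existing visit
  expect_true(all(tr$dispensing$visit_id %in% tr$visits$visit_id))
  # questionnaire visits exist
  expect_true(all(q$visit_id %in% tr$visits$visit_id))
  # only participants enrolled >= 2 months generate visits
  costed <- p$participant_id[p$months_enrolled >= 2]
  expect_true(all(tr$visits$participant_id %in% costed))
  # subsample size close to the requested fraction
  expect_equal(nrow(q) / sum(p$months_enrolled >= 2),
               small_config()$subsample_fraction, tolerance = 0.05)
})

test_that("generator hits requested moments (published-magnitude anchor)", {
  # no facility-level noise so visits are iid and the SE bound is exact
  cfg <- trial_config(
    n_participants = 700L, n_facilities = c(Uganda = 4L),
    country_share = c(Uganda = 1), multimorbid_fraction = 0,
    single_mix = c(HIV = 1, HTN = 0, DM = 0), subsample_fraction = 0,
    visits_per_year = 6, short_fraction = 0, facility_cv = 0)
  tr <- generate_trial(cfg, seed = 21)
  rates <- allocate_all(tr$ledgers)
  prov <- provider_visit_costs(tr$visits, rates, tr$dispensing, cfg$economy)
  m <- sample_moments(prov, "total", c("country", "arm", "profile"))
  expect_true(all(m$n >= 1000))
  for (i in seq_len(nrow(m))) {
    expect_lt(abs(m$mean[i] - 168.85), 3 * 45.49 / sqrt(m$n[i]))
  }
  # 4-sigma moment-targeting bound across independent seeds
  for (s in 22:26) {
    tr <- generate_trial(cfg, seed = s)
    prov <- provider_visit_costs(tr$visits, allocate_all(tr$ledgers),
                                 tr$dispensing, cfg$economy)
    expect_lt(abs(mean(prov$total) - 168.85),
              4 * 45.49 / sqrt(nrow(prov)))
  }
})

test_that("sample_moments matches hand computation and flags small groups", {
  df <- data.frame(g = c("a", "a", "b"), v = c(0, 2, 5))
  m <- sample_moments(df, "v", "g")
  expect_equal(m$mean, c(1, 5))
  expect_equal(m$sd, c(sqrt(2), NA_real_)) # n-1 denominator; n=1 has no sd
  expect_equal(m$n, c(2L, 1L))
  expect_error(sample_moments(df[0, ], "v", "g"), "nonempty")
  # brute-force oracle on grouped random data
  set.seed(42)
  big <- data.frame(g = sample(letters[1:4], 200, TRUE), v = rnorm(200))
  m <- sample_moments(big, "v", "g")
  for (i in seq_len(nrow(m))) {
    vv <- big$v[big$g == m$g[i]]
    expect_equal(m$mean[i], sum(vv) / length(vv))
    expect_equal(m$sd[i], sqrt(sum((vv - mean(vv))^2) / (length(vv) - 1)))
  }
})

test_that("invalid configurations are rejected with the offending field", {
  expect_error(trial_config(n_participants = -5), "n_participants")
  expect_error(trial_config(multimorbid_fraction = 1.2),
               "multimorbid_fraction")
  expect_error(trial_config(facility_cv = -0.1), "facility_cv")
  expect_error(trial_config(single_mix = c(HIV = 0.7, HTN = 0.2, DM = 0.2)),
               "single_mix")
  expect_error(
    trial_config(provider_targets = data.frame(
      country = "Uganda", condition = "HIV", mean = 100, sd = -1)),
    "sd")
})

test_that("lognormal family also targets the requested moments", {
  cfg <- trial_config(
    n_participants = 500L, n_facilities = c(Uganda = 4L),
    country_share = c(Uganda = 1), multimorbid_fraction = 0,
    single_mix = c(HIV = 1, HTN = 0, DM = 0), subsample_fraction = 0,
    visits_per_year = 6, short_fraction = 0, facility_cv = 0,
    family = "lognormal")
  tr <- generate_trial(cfg, seed = 9)
  prov <- provider_visit_costs(tr$visits, allocate_all(tr$ledgers),
                               tr$dispensing, cfg$economy)
  expect_lt(abs(mean(prov$total) - 168.85), 4 * 45.49 / sqrt(nrow(prov)))
  expect_true(all(prov$total >= 0))
})
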