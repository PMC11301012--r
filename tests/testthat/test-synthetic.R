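test_that("generation is byte-identical under a fixed config and seed", {
  cfg <- synthetic_config(n_participants = 25, seed = 99)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  generate_cohort(cfg, dir = d1)
  generate_cohort(cfg, dir = d2)
  for (f in c("measurements.csv", "labs.csv", "questionnaires.csv",
              "ground_truth.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("invalid configurations are rejected before any output", {
  expect_error(synthetic_config(female_fraction = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(grade_prevalence = c(none = 0.5, grade1 = 0.2,
                                                     grade2 = 0.2, grade3 = 0.2)),
               "sum to 1")
  bad_lo <- matrix(0.5, 5, 5, dimnames = list(category_names(),
                                              category_names()))
  expect_error(synthetic_config(pairwise_log_odds = bad_lo), "diagonal")
})

test_that("an all-normotensive cohort is never notified", {
  cfg <- synthetic_config(n_participants = 40, seed = 5,
                          grade_prevalence = c(none = 1, grade1 = 0,
                                               grade2 = 0, grade3 = 0),
                          bp_noise_sd = 2)
  co <- generate_cohort(cfg)
  av <- period_averages(co$measurements, start_date = cfg$start_date)
  tri <- triage_cohort(av, cfg$policy, cfg$thresholds)
  expect_equal(sum(tri$triggered), 0)
})

test_that("noiseless full-adherence grade3 cohort is notified with
           sensitivity and specificity 1", {
  cfg <- synthetic_config(
    n_participants = 60, seed = 6, bp_noise_sd = 0,
    adherence = c(morning = 1, midday = 1, evening = 1),
    grade_prevalence = c(none = 0.5, grade1 = 0.2, grade2 = 0.1,
                         grade3 = 0.2))
  co <- generate_cohort(cfg)
  rec <- recover_parameters(co)
  expect_equal(rec$triage$estimate[rec$triage$measure == "sensitivity"], 1)
  expect_equal(rec$triage$estimate[rec$triage$measure == "specificity"], 1)
})

test_that("lab panels encode the latent flags exactly", {
  cfg <- synthetic_config(n_participants = 300, seed = 8)
  co <- generate_cohort(cfg, components = "labs")
  recovered <- categorize_panels(co$labs)
  for (cat in category_names())
    expect_equal(recovered[[cat]], co$ground_truth[[paste0("true_", cat)]])
})

test_that("marginal flag rates and demographics match the configuration", {
  cfg <- synthetic_config(n_participants = 5000, seed = 9)
  co <- generate_cohort(cfg, components = "labs")
  gt <- co$ground_truth
  # binomial 99.9% bands around the configured rates
  for (cat in category_names()) {
    rate <- mean(gt[[paste0("true_", cat)]])
    p0 <- cfg$category_base_rates[[cat]]
    expect_lt(abs(rate - p0), 3.3 * sqrt(p0 * (1 - p0) / 5000))
  }
  p_f <- cfg$female_fraction
  expect_lt(abs(mean(gt$sex == "female") - p_f),
            3.3 * sqrt(p_f * (1 - p_f) / 5000))
  # bimodality: both age modes populated, trough between them
  expect_gt(mean(gt$age >= 25 & gt$age < 45), 0.3)
  expect_gt(mean(gt$age >= 55 & gt$age < 75), 0.3)
  expect_lt(mean(gt$age >= 45 & gt$age < 55), 0.2)
})

test_that("sampled flags reproduce a configured pairwise odds ratio", {
  lo <- matrix(0, 5, 5, dimnames = list(category_names(), category_names()))
  lo["blood_sugar", "lipid"] <- lo["lipid", "blood_sugar"] <- log(8)
  set.seed(10)
  flags <- sample_category_flags(
    20000, c(blood_sugar = 0.465, renal = 0.398, lipid = 0.354,
             hematological = 0.165, liver = 0.110), lo)
  a <- sum(flags[, "blood_sugar"] & flags[, "lipid"])
  b <- sum(flags[, "blood_sugar"] & !flags[, "lipid"])
  c <- sum(!flags[, "blood_sugar"] & flags[, "lipid"])
  d <- sum(!flags[, "blood_sugar"] & !flags[, "lipid"])
  or <- (a * d) / (b * c)
  expect_gt(or, 8 * 0.85)
  expect_lt(or, 8 / 0.85)
  # marginals still calibrated under the coupling
  expect_lt(abs(mean(flags[, "blood_sugar"]) - 0.465), 0.015)
  expect_lt(abs(mean(flags[, "lipid"]) - 0.354), 0.015)
})

test_that("care transitions and notification condition the questionnaires", {
  cfg <- synthetic_config(
    n_participants = 800, seed = 12,
    grade_prevalence = c(none = 0.4, grade1 = 0.2, grade2 = 0.1,
                         grade3 = 0.3),
    care_transition = list(to_regular_notified = 0.7,
                           to_regular_unnotified = 0.1,
                           stay_regular_notified = 0.95,
                           stay_regular_unnotified = 0.9))
  co <- generate_cohort(cfg)
  rec <- recover_parameters(co)
  tr <- rec$transitions
  for (i in seq_len(nrow(tr))) {
    if (tr$n[i] >= 20) {
      expect_gte(tr$configured[i], tr$lower[i])
      expect_lte(tr$configured[i], tr$upper[i])
    }
  }
  # notified non-treated participants move to regular care more often
  est <- setNames(tr$estimate, tr$transition)
  expect_gt(est[["to_regular_notified"]], est[["to_regular_unnotified"]])
})
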