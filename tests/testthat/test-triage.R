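make_averages <- function(id = "A", morning = NULL, midday = NULL,
                          evening = NULL) {
  row <- function(p, v) {
    if (is.null(v))
      data.frame(participant_id = id, period = p, n_used = 0L,
                 mean_sbp = NA_real_, mean_dbp = NA_real_)
    else
      data.frame(participant_id = id, period = p, n_used = as.integer(v[3]),
                 mean_sbp = v[1], mean_dbp = v[2])
  }
  rbind(row("morning", morning), row("midday", midday),
        row("evening", evening))
}

test_that("grade_bp returns the highest band met by either component", {
  expect_equal(grade_bp(185, 95), "grade3")   # systolic alone
  expect_equal(grade_bp(150, 112), "grade3")  # diastolic alone
  expect_equal(grade_bp(160, 100), "grade2")  # band edge, >= convention
  expect_equal(grade_bp(140, 90), "grade1")
  expect_equal(grade_bp(120, 70), "none")
  expect_error(grade_bp(-5, 70), "positive")
  expect_error(grade_thresholds(grade2 = c(sbp = 190, dbp = 100)),
               "increasing")
})

test_that("notification requires at least three retained measurements", {
  g3 <- notification_policy("grade3_only")
  res <- evaluate_notification(make_averages(morning = c(185, 112, 3)), g3)
  expect_true(res$triggered)
  expect_equal(res$grade, "grade3")
  expect_equal(res$qualifying_periods, "morning")

  # same average on two measurements: never notified
  res2 <- evaluate_notification(make_averages(morning = c(185, 112, 2)), g3)
  expect_false(res2$triggered)
  expect_length(res2$qualifying_periods, 0)
})

test_that("the policy phase decides whether Grade II triggers", {
  av <- make_averages(morning = c(165, 95, 5))
  expect_false(evaluate_notification(av, notification_policy("grade3_only"))$triggered)
  r2 <- evaluate_notification(av, notification_policy("grade2_plus"))
  expect_true(r2$triggered)
  expect_equal(r2$grade, "grade2")

  expect_equal(policy_for_date(as.Date("2014-06-30"))$label, "grade2_plus")
  expect_equal(policy_for_date(as.Date("2014-07-01"))$label, "grade3_only")
})

test_that("all-empty averages yield a no-eligible-period result", {
  res <- evaluate_notification(make_averages(), notification_policy("grade3_only"))
  expect_false(res$triggered)
  expect_true(any(grepl("no eligible period", res$reasons)))
})

test_that("grade is the maximum over eligible periods", {
  av <- make_averages(morning = c(165, 102, 4), evening = c(184, 111, 5))
  res <- evaluate_notification(av, notification_policy("grade3_only"))
  expect_equal(res$grade, "grade3")
  expect_equal(res$qualifying_periods, "evening")
})

test_that("triage never qualifies a sparse period, policies nest, and
           raising systolic pressure never revokes a notification", {
  set.seed(41)
  av <- random_averages(300)
  g2 <- notification_policy("grade2_plus")
  g3 <- notification_policy("grade3_only")
  for (id in unique(av$participant_id)) {
    one <- av[av$participant_id == id, ]
    r2 <- evaluate_notification(one, g2)
    r3 <- evaluate_notification(one, g3)
    for (r in list(r2, r3)) {
      qn <- one$n_used[match(r$qualifying_periods, one$period)]
      expect_true(all(qn >= 3))
    }
    if (r3$triggered) expect_true(r2$triggered)
    if (r2$triggered) {
      bumped <- one
      bumped$mean_sbp <- bumped$mean_sbp + sample(1:40, 1)
      expect_true(evaluate_notification(bumped, g2)$triggered)
    }
  }
})

test_that("letters are deterministic and carry grade, values and lab lines", {
  av <- make_averages(morning = c(185.2, 112.4, 3))
  res <- evaluate_notification(av, notification_policy("grade3_only"))
  flags <- c(blood_sugar = TRUE, renal = FALSE, lipid = FALSE,
             hematological = FALSE, liver = FALSE)
  letter <- compose_letter(res, flags = flags, averages = av)
  expect_identical(letter, compose_letter(res, flags = flags, averages = av))
  expect_match(letter, "Grade III hypertension")
  expect_match(letter, "185.2/112.4", fixed = TRUE)
  expect_match(letter, "blood sugar")

  no_flags <- compose_letter(res, flags = flags & FALSE, averages = av)
  expect_false(grepl("abnormal values", no_flags))

  not_triggered <- evaluate_notification(make_averages(morning = c(120, 70, 5)),
                                         notification_policy("grade3_only"))
  expect_error(compose_letter(not_triggered), "triggered")
})

test_that("triage_cohort mirrors per-participant evaluation", {
  set.seed(43)
  av <- random_averages(25)
  tri <- triage_cohort(av, notification_policy("grade2_plus"))
  expect_equal(nrow(tri), 25)
  for (i in sample(25, 5)) {
    id <- tri$participant_id[i]
    r <- evaluate_notification(av[av$participant_id == id, ],
                               notification_policy("grade2_plus"))
    expect_equal(tri$triggered[i], r$triggered)
    expect_equal(tri$grade[i], r$grade)
  }
})
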