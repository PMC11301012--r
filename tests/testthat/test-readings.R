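test_that("assign_period maps clock times to the protocol windows", {
  expect_equal(assign_period("2014-03-01T06:30"),
               data.frame(period = "morning",
                          logical_day = as.Date("2014-03-01")))
  # before 04:00 belongs to the previous day's evening
  expect_equal(assign_period("2014-03-02T02:00"),
               data.frame(period = "evening",
                          logical_day = as.Date("2014-03-01")))
  # half-open boundaries: 11:00 opens midday, 16:00 opens evening
  expect_equal(assign_period("2014-03-01T11:00")$period, "midday")
  expect_equal(assign_period("2014-03-01T16:00")$period, "evening")
  expect_equal(assign_period("2014-03-01T04:00")$period, "morning")
  expect_error(assign_period("2014-03-01 25:61"), "unparseable")
})

test_that("the three windows partition every minute of the day", {
  ts <- sprintf("2014-05-10T%02d:%02d", rep(0:23, each = 60), 0:59)
  pa <- assign_period(ts)
  expect_equal(nrow(pa), 1440)
  expect_true(all(pa$period %in% c("morning", "midday", "evening")))
  expect_equal(sum(pa$period == "morning"), 7 * 60)
  expect_equal(sum(pa$period == "midday"), 5 * 60)
  expect_equal(sum(pa$period == "evening"), 12 * 60)
})

test_that("dedup keeps the first reading per day-period cell", {
  m <- data.frame(participant_id = "A",
                  timestamp = c("2014-03-01T07:00", "2014-03-01T06:00"),
                  sbp = c(150, 130), dbp = c(95, 80),
                  stringsAsFactors = FALSE)
  out <- dedup_first_per_period(m)
  expect_equal(nrow(out), 1)
  expect_equal(out$sbp, 130)

  single <- m[1, , drop = FALSE]
  expect_equal(dedup_first_per_period(single)$sbp, 150)

  # 23:00 and next-day 02:00 share the same evening cell
  m2 <- data.frame(participant_id = "A",
                   timestamp = c("2014-03-01T23:00", "2014-03-02T02:00"),
                   sbp = c(140, 145), dbp = c(85, 90),
                   stringsAsFactors = FALSE)
  out2 <- dedup_first_per_period(m2)
  expect_equal(out2$timestamp, "2014-03-01T23:00")
})

test_that("dedup is idempotent and warns on identical timestamps", {
  set.seed(11)
  m <- random_stream(40)
  once <- dedup_first_per_period(m)
  twice <- dedup_first_per_period(once[names(m)])
  expect_equal(twice[names(m)], once[names(m)])

  dup <- data.frame(participant_id = "A",
                    timestamp = rep("2014-03-01T06:00", 2),
                    sbp = c(130, 150), dbp = c(80, 95),
                    stringsAsFactors = FALSE)
  expect_warning(out <- dedup_first_per_period(dup), "duplicate")
  expect_equal(out$sbp, 130)
})

test_that("period averages match a naive double-loop oracle", {
  expect_arithmetic <- function(meas) {
    got <- suppressWarnings(period_averages(meas))  # random ties in fixture
    oracle <- period_average_oracle(meas)
    for (p in c("morning", "midday", "evening")) {
      row <- got[got$period == p, ]
      expect_equal(row$n_used, oracle[[p]]$n)
      expect_equal(row$mean_sbp, oracle[[p]]$sbp)
      expect_equal(row$mean_dbp, oracle[[p]]$dbp)
    }
  }
  # worked example: three morning readings average to 185/112
  m <- data.frame(participant_id = "A",
                  timestamp = sprintf("2014-03-%02dT06:30", 1:3),
                  sbp = c(180, 190, 185), dbp = c(110, 114, 112),
                  stringsAsFactors = FALSE)
  got <- period_averages(m)
  expect_equal(got$mean_sbp[got$period == "morning"], 185)
  expect_equal(got$mean_dbp[got$period == "morning"], 112)
  expect_equal(got$n_used[got$period == "morning"], 3)
  expect_equal(got$n_used[got$period == "evening"], 0)
  expect_true(is.na(got$mean_sbp[got$period == "evening"]))

  set.seed(21)
  for (rep in 1:10) expect_arithmetic(random_stream(sample(1:100, 1)))
})

test_that("after dedup each period holds at most 14 readings in a window", {
  set.seed(31)
  m <- random_stream(200)
  out <- suppressWarnings(period_averages(m, start_date = as.Date("2014-03-01")))
  expect_true(all(out$n_used <= 14))
})

test_that("readings outside the monitoring window are dropped with warning", {
  m <- data.frame(participant_id = "A",
                  timestamp = c("2014-03-01T06:00", "2014-04-01T06:00"),
                  sbp = c(130, 140), dbp = c(80, 85),
                  stringsAsFactors = FALSE)
  expect_warning(out <- period_averages(m, start_date = as.Date("2014-03-01")),
                 "outside")
  expect_equal(out$n_used[out$period == "morning"], 1)
})

test_that("empty and invalid measurement streams are handled", {
  empty <- data.frame(participant_id = character(0),
                      timestamp = character(0),
                      sbp = numeric(0), dbp = numeric(0))
  expect_equal(nrow(period_averages(empty)), 0)
  bad <- data.frame(participant_id = "A", timestamp = "2014-03-01T06:00",
                    sbp = 80, dbp = 95)
  expect_error(period_averages(bad), "sbp > dbp")
})
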