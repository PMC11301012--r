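# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and dhyper, which fisher_exact uses): the Fisher
# oracle enumerates tables with choose(), the period-average oracle is a
# naive double loop.

# Brute-force two-sided Fisher p: enumerate every table with the observed
# margins via binomial coefficients and sum point probabilities <= observed.
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, c1 - (c + d)):min(r1, c1)
  prob <- choose(r1, support) * choose(n - r1, c1 - support) / choose(n, c1)
  p_obs <- prob[match(a, support)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Naive per-period averaging: loop over (logical day, period) cells, keep
# the chronologically first reading in each, then average per period.
period_average_oracle <- function(meas) {
  ts <- strsplit(meas$timestamp, "T", fixed = TRUE)
  date <- as.Date(vapply(ts, `[`, character(1), 1))
  hm <- strsplit(vapply(ts, `[`, character(1), 2), ":", fixed = TRUE)
  minute <- as.numeric(vapply(hm, `[`, character(1), 1)) * 60 +
    as.numeric(vapply(hm, `[`, character(1), 2))
  period <- ifelse(minute < 240, "evening",
            ifelse(minute < 660, "morning",
            ifelse(minute < 960, "midday", "evening")))
  lday <- date - (minute < 240)
  keep <- logical(nrow(meas))
  for (day in unique(as.character(lday))) {
    for (p in c("morning", "midday", "evening")) {
      cell <- which(as.character(lday) == day & period == p)
      if (length(cell) > 0) {
        abs_min <- as.numeric(date[cell]) * 1440 + minute[cell]
        keep[cell[which.min(abs_min)]] <- TRUE
      }
    }
  }
  out <- list()
  for (p in c("morning", "midday", "evening")) {
    sel <- keep & period == p
    out[[p]] <- list(n = sum(sel),
                     sbp = if (any(sel)) mean(meas$sbp[sel]) else NA_real_,
                     dbp = if (any(sel)) mean(meas$dbp[sel]) else NA_real_)
  }
  out
}

# Random measurement stream for one participant over a 14-day window.
random_stream <- function(n, id = "X1", start = as.Date("2014-03-01")) {
  minute <- sample(0:1439, n, replace = TRUE)
  day <- start + sample(0:13, n, replace = TRUE)
  dbp <- sample(60:110, n, replace = TRUE)
  data.frame(
    participant_id = id,
    timestamp = sprintf("%sT%02d:%02d", format(day, "%Y-%m-%d"),
                        minute %/% 60, minute %% 60),
    sbp = dbp + sample(20:80, n, replace = TRUE),
    dbp = dbp, stringsAsFactors = FALSE)
}

# Random period-average records for a cohort of synthetic participants.
random_averages <- function(n_participants) {
  rows <- list()
  for (i in seq_len(n_participants)) {
    n_used <- sample(0:6, 3, replace = TRUE)
    sbp <- round(runif(3, 100, 220), 1)
    dbp <- round(pmin(sbp - 10, runif(3, 60, 130)), 1)
    rows[[i]] <- data.frame(
      participant_id = sprintf("R%04d", i),
      period = c("morning", "midday", "evening"),
      n_used = n_used,
      mean_sbp = ifelse(n_used > 0, sbp, NA_real_),
      mean_dbp = ifelse(n_used > 0, dbp, NA_real_),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# All-normal laboratory panel (midpoints of the reference ranges).
normal_panel <- function(id = "L1", sex = "male") {
  rr <- reference_ranges()
  mid <- function(an) {
    r <- rr[rr$analyte == an & rr$sex %in% c("both", sex), ]
    (r$low + r$high) / 2
  }
  data.frame(participant_id = id, sex = sex, crp = mid("crp"),
             hemoglobin = mid("hemoglobin"), platelets = mid("platelets"),
             leukocytes = mid("leukocytes"), blood_sugar = mid("blood_sugar"),
             ast = mid("ast"), alt = mid("alt"),
             creatinine = mid("creatinine"), bun = mid("bun"),
             uric_acid = mid("uric_acid"), sodium = mid("sodium"),
             blast_cells = FALSE, atypical_cells = FALSE,
             erythroblasts_per_200 = 0L, lipid_abnormal = FALSE,
             stringsAsFactors = FALSE)
}
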