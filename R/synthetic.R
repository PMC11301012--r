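#' Configuration of the synthetic screening cohort
#'
#' Parameters of the generator used to validate every pipeline stage without
#' real data. Demographics emulate a community cohort with a bimodal age
#' distribution (peaks in the 30s and 60s) and roughly twice as many women
#' as men. Each participant carries a latent hypertension grade with a true
#' blood pressure inside the grade band; 14 days of readings are produced
#' with time-of-day adherence, occasional same-period repeats and additive
#' measurement noise. Laboratory abnormality category flags follow a
#' pairwise log-linear model whose main effects are calibrated so marginal
#' rates match \code{category_base_rates} under the configured couplings;
#' analyte values are drawn just outside (or inside) the reference bounds so
#' the flagging stage recovers the intended flags exactly. Pre/post
#' questionnaire behaviour follows a care-transition model conditioned on
#' whether the triage stage notifies the participant.
#'
#' @param n_participants cohort size.
#' @param seed default RNG seed used by \code{\link{generate_cohort}}.
#' @param female_fraction probability a participant is female (default 2/3).
#' @param age_mixture list with numeric \code{means}, \code{sds},
#'   \code{weights} of a two-component normal age mixture (years).
#' @param grade_prevalence named probabilities over
#'   \code{c("none","grade1","grade2","grade3")}.
#' @param adherence named per-day measurement probabilities for
#'   \code{morning}, \code{midday}, \code{evening}.
#' @param repeat_rate Poisson mean of extra same-period readings beyond the
#'   first in a cell where a measurement occurs.
#' @param bp_noise_sd within-person systolic measurement standard deviation,
#'   mmHg (diastolic noise is scaled by 0.7).
#' @param start_date first day of every participant's 14-day window.
#' @param category_base_rates named marginal probabilities of the five
#'   abnormality categories.
#' @param pairwise_log_odds symmetric 5x5 matrix (zero diagonal) of pairwise
#'   log odds ratios coupling the category flags; dimnames must be the
#'   category names.
#' @param abnormal_band relative width of the band just outside a reference
#'   bound from which abnormal analyte values are drawn.
#' @param pre_category_probs named probabilities of the five substantive
#'   pre-survey answers.
#' @param care_transition list of probabilities: \code{to_regular_notified},
#'   \code{to_regular_unnotified} (a non-treated participant moves to
#'   regular treatment), \code{stay_regular_notified},
#'   \code{stay_regular_unnotified}.
#' @param response_rates named probabilities that the \code{pre} and
#'   \code{post} questionnaires are answered.
#' @param policy \code{\link{notification_policy}} used when simulating the
#'   notification that conditions the care transition.
#' @param thresholds \code{\link{grade_thresholds}}.
#' @return an object of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(
    n_participants = 500,
    seed = 1L,
    female_fraction = 2 / 3,
    age_mixture = list(means = c(35, 65), sds = c(7, 7), weights = c(0.5, 0.5)),
    grade_prevalence = c(none = 0.70, grade1 = 0.20, grade2 = 0.07,
                         grade3 = 0.03),
    adherence = c(morning = 0.90, midday = 0.20, evening = 0.85),
    repeat_rate = 0.1,
    bp_noise_sd = 8,
    start_date = as.Date("2014-03-01"),
    category_base_rates = c(blood_sugar = 0.465, renal = 0.398,
                            lipid = 0.354, hematological = 0.165,
                            liver = 0.110),
    pairwise_log_odds = NULL,
    abnormal_band = 0.3,
    pre_category_probs = c(regular_treatment = 0.42,
                           discontinued_followup = 0.07,
                           lifestyle_precaution = 0.17,
                           followup_no_medication = 0.10,
                           never_pointed_out = 0.24),
    care_transition = list(to_regular_notified = 0.55,
                           to_regular_unnotified = 0.10,
                           stay_regular_notified = 0.95,
                           stay_regular_unnotified = 0.90),
    response_rates = c(pre = 0.90, post = 0.65),
    policy = notification_policy("grade3_only"),
    thresholds = grade_thresholds()) {
  cats <- category_names()
  if (is.null(pairwise_log_odds)) {
    pairwise_log_odds <- matrix(0, 5, 5, dimnames = list(cats, cats))
  }
  probs <- c(female_fraction, grade_prevalence, adherence,
             category_base_rates, pre_category_probs,
             unlist(care_transition), response_rates)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (abs(sum(grade_prevalence) - 1) > 1e-8)
    stop("grade_prevalence must sum to 1")
  if (abs(sum(pre_category_probs) - 1) > 1e-8)
    stop("pre_category_probs must sum to 1")
  if (!isTRUE(all.equal(pairwise_log_odds, t(pairwise_log_odds))) ||
      any(diag(pairwise_log_odds) != 0))
    stop("pairwise_log_odds must be symmetric with zero diagonal")
  if (!identical(dimnames(pairwise_log_odds), list(cats, cats)))
    stop("pairwise_log_odds dimnames must be the five category names")
  if (repeat_rate < 0 || bp_noise_sd < 0 || abnormal_band <= 0)
    stop("repeat_rate and bp_noise_sd must be >= 0; abnormal_band > 0")
  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    female_fraction = female_fraction, age_mixture = age_mixture,
    grade_prevalence = grade_prevalence, adherence = adherence,
    repeat_rate = repeat_rate, bp_noise_sd = bp_noise_sd,
    start_date = as.Date(start_date),
    category_base_rates = category_base_rates,
    pairwise_log_odds = pairwise_log_odds, abnormal_band = abnormal_band,
    pre_category_probs = pre_category_probs,
    care_transition = care_transition, response_rates = response_rates,
    policy = policy, thresholds = thresholds),
    class = "synthetic_config")
}

# Enumerate the 2^5 flag configurations and their log-linear probabilities.
flag_model_joint <- function(alpha, log_odds) {
  k <- length(alpha)
  states <- as.matrix(expand.grid(rep(list(0:1), k)))
  colnames(states) <- names(alpha)
  logw <- states %*% alpha + rowSums((states %*% log_odds) * states) / 2
  w <- exp(logw - max(logw))
  list(states = states, prob = as.numeric(w / sum(w)))
}

# Calibrate main effects so the model's marginals hit the target rates under
# the given couplings (coordinate-wise logit fixed point on the enumerated
# joint; exact up to the stated tolerance).
calibrate_flag_model <- function(base_rates, log_odds, tol = 1e-10,
                                 max_iter = 500) {
  target <- pmin(pmax(base_rates, 1e-12), 1 - 1e-12)
  alpha <- stats::qlogis(target)
  for (i in seq_len(max_iter)) {
    joint <- flag_model_joint(alpha, log_odds)
    marg <- as.numeric(crossprod(joint$states, joint$prob))
    if (max(abs(marg - target)) < tol) break
    alpha <- alpha + stats::qlogis(target) - stats::qlogis(marg)
  }
  list(alpha = alpha, joint = flag_model_joint(alpha, log_odds))
}

#' Sample correlated abnormality-category flags
#'
#' Draws category flag vectors from the pairwise log-linear model by exact
#' enumeration of the 32 joint configurations, after calibrating the main
#' effects so marginal rates match \code{base_rates} under the couplings.
#' The pairwise log odds ratio of any two categories in the sampled joint
#' equals the configured coupling when the pair is not embedded in a larger
#' coupled component.
#'
#' @param n number of participants.
#' @param base_rates named marginal probabilities over the five categories.
#' @param log_odds symmetric 5x5 pairwise log-odds-ratio matrix.
#' @return logical matrix, \code{n} rows by five category columns.
#' @export
sample_category_flags <- function(n, base_rates, log_odds = NULL) {
  cats <- category_names()
  if (is.null(log_odds))
    log_odds <- matrix(0, 5, 5, dimnames = list(cats, cats))
  base_rates <- base_rates[cats]
  fit <- calibrate_flag_model(base_rates, log_odds)
  idx <- sample.int(nrow(fit$joint$states), n, replace = TRUE,
                    prob = fit$joint$prob)
  flags <- fit$joint$states[idx, , drop = FALSE] == 1
  rownames(flags) <- NULL
  flags
}

range_for <- function(ranges, analyte, sex) {
  r <- ranges[ranges$analyte == analyte, , drop = FALSE]
  if (nrow(r) == 1) r[rep(1, length(sex)), c("low", "high")]
  else r[match(sex, r$sex), c("low", "high")]
}

# Draw n values uniformly inside the (sex-specific) reference range.
draw_normal_values <- function(ranges, analyte, sex) {
  r <- range_for(ranges, analyte, sex)
  stats::runif(length(sex), r$low, r$high)
}

# Draw values just outside a reference bound: in (high, high*(1+band)] or
# [low*(1-band), low). A 1% relative margin keeps the draw outside the bound
# after values are rounded for the CSV.
draw_abnormal_values <- function(ranges, analyte, sex, side, band) {
  r <- range_for(ranges, analyte, sex)
  if (side == "high") stats::runif(length(sex), r$high * 1.01, r$high * (1 + band))
  else stats::runif(length(sex), r$low * (1 - band), r$low * 0.99)
}

generate_labs <- function(ids, sex, flags, band,
                          ranges = reference_ranges()) {
  n <- length(ids)
  labs <- data.frame(participant_id = ids, sex = sex,
                     stringsAsFactors = FALSE)
  for (an in c("crp", "hemoglobin", "platelets", "leukocytes",
               "blood_sugar", "ast", "alt", "creatinine", "bun",
               "uric_acid", "sodium"))
    labs[[an]] <- draw_normal_values(ranges, an, sex)
  labs$blast_cells <- rep(FALSE, n)
  labs$atypical_cells <- rep(FALSE, n)
  labs$erythroblasts_per_200 <- sample(0:5, n, replace = TRUE)
  labs$lipid_abnormal <- as.logical(flags[, "lipid"])

  i <- which(flags[, "blood_sugar"])
  if (length(i))
    labs$blood_sugar[i] <- draw_abnormal_values(ranges, "blood_sugar",
                                                sex[i], "high", band)
  i <- which(flags[, "renal"])
  if (length(i)) {
    pick <- sample(c("creatinine", "bun"), length(i), replace = TRUE)
    for (an in c("creatinine", "bun")) {
      j <- i[pick == an]
      if (length(j))
        labs[[an]][j] <- draw_abnormal_values(ranges, an, sex[j], "high", band)
    }
  }
  i <- which(flags[, "liver"])
  if (length(i)) {
    pick <- sample(c("ast", "alt"), length(i), replace = TRUE)
    for (an in c("ast", "alt")) {
      j <- i[pick == an]
      if (length(j))
        labs[[an]][j] <- draw_abnormal_values(ranges, an, sex[j], "high", band)
    }
  }
  i <- which(flags[, "hematological"])
  if (length(i)) {
    mech <- sample(c("hemoglobin_low", "platelets_high", "leukocytes_high",
                     "morphology"), length(i), replace = TRUE)
    j <- i[mech == "hemoglobin_low"]
    if (length(j))
      labs$hemoglobin[j] <- draw_abnormal_values(ranges, "hemoglobin",
                                                 sex[j], "low", band)
    j <- i[mech == "platelets_high"]
    if (length(j))
      labs$platelets[j] <- draw_abnormal_values(ranges, "platelets",
                                                sex[j], "high", band)
    j <- i[mech == "leukocytes_high"]
    if (length(j))
      labs$leukocytes[j] <- draw_abnormal_values(ranges, "leukocytes",
                                                 sex[j], "high", band)
    j <- i[mech == "morphology"]
    if (length(j)) {
      blast <- stats::runif(length(j)) < 0.5
      labs$blast_cells[j] <- blast
      labs$erythroblasts_per_200[j][!blast] <-
        sample(31:60, sum(!blast), replace = TRUE)
    }
  }
  num <- vapply(labs, is.numeric, logical(1))
  labs[num] <- lapply(labs[num], function(x) round(x, 2))
  labs$leukocytes <- round(labs$leukocytes)
  labs$erythroblasts_per_200 <- as.integer(labs$erythroblasts_per_200)
  labs
}

bp_bands <- list(
  none   = list(sbp = c(105, 139), dbp = c(65, 85)),
  grade1 = list(sbp = c(140, 159), dbp = c(90, 99)),
  grade2 = list(sbp = c(160, 179), dbp = c(100, 109)),
  grade3 = list(sbp = c(180, 205), dbp = c(110, 125)))

period_windows <- list(morning = c(240, 660), midday = c(660, 960),
                       evening = c(960, 1680))

generate_measurements <- function(ids, true_sbp, true_dbp, config) {
  n <- length(ids)
  grid <- expand.grid(pi = seq_len(n), day = 1:14,
                      period = bp_periods, stringsAsFactors = FALSE)
  grid <- grid[order(grid$pi, grid$day, match(grid$period, bp_periods)), ]
  p_adhere <- config$adherence[grid$period]
  present <- stats::runif(nrow(grid)) < p_adhere
  extra <- stats::rpois(nrow(grid), config$repeat_rate) * present
  count <- present + extra
  grid <- grid[rep(seq_len(nrow(grid)), count), , drop = FALSE]
  if (nrow(grid) == 0)
    return(data.frame(participant_id = character(0), timestamp = character(0),
                      sbp = integer(0), dbp = integer(0),
                      stringsAsFactors = FALSE))
  win_lo <- vapply(period_windows, `[`, numeric(1), 1)[grid$period]
  win_hi <- vapply(period_windows, `[`, numeric(1), 2)[grid$period]
  minute <- floor(win_lo + stats::runif(nrow(grid)) * (win_hi - win_lo - 10))
  # distinct minutes within a day-period cell so timestamps never collide
  key <- paste(grid$pi, grid$day, grid$period)
  repeat {
    dup <- duplicated(paste(key, minute))
    if (!any(dup)) break
    minute[dup] <- minute[dup] + 1
  }
  day <- config$start_date + grid$day - 1
  cal_day <- day + (minute >= 1440)
  cal_minute <- minute %% 1440
  noise_s <- stats::rnorm(nrow(grid), 0, config$bp_noise_sd)
  noise_d <- stats::rnorm(nrow(grid), 0, 0.7 * config$bp_noise_sd)
  sbp <- round(true_sbp[grid$pi] + noise_s)
  dbp <- pmax(40, round(true_dbp[grid$pi] + noise_d))
  sbp <- pmax(sbp, dbp + 5)
  out <- data.frame(participant_id = ids[grid$pi],
                    timestamp = format_timestamp(cal_day, cal_minute),
                    sbp = as.integer(sbp), dbp = as.integer(dbp),
                    stringsAsFactors = FALSE)
  out <- out[order(out$participant_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a synthetic screening cohort
#'
#' Produces, per participant: demographics; a latent hypertension grade and
#' true blood pressure; a 14-day measurement stream; a laboratory panel
#' encoding correlated abnormality-category flags; pre/post questionnaire
#' responses whose care transition is conditioned on whether the triage
#' stage (run on the generated measurements under the configured policy)
#' notifies the participant; and a ground-truth record of all latent values.
#' Output is fully determined by \code{config} and \code{seed}.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param seed RNG seed (defaults to \code{config$seed}).
#' @param dir optional directory: when given, writes
#'   \code{measurements.csv}, \code{labs.csv}, \code{questionnaires.csv} and
#'   \code{ground_truth.csv} there.
#' @param components which data to generate, a subset of
#'   \code{c("measurements","labs","questionnaires")}; questionnaires
#'   require measurements (the transition depends on the triage outcome).
#' @return (invisibly when \code{dir} is given) a list of class
#'   \code{"synthetic_cohort"} with elements \code{measurements},
#'   \code{labs}, \code{questionnaires}, \code{ground_truth} and
#'   \code{config}.
#' @export
generate_cohort <- function(config = synthetic_config(), seed = config$seed,
                            dir = NULL,
                            components = c("measurements", "labs",
                                           "questionnaires")) {
  stopifnot(inherits(config, "synthetic_config"))
  if ("questionnaires" %in% components &&
      !"measurements" %in% components)
    stop("questionnaires require measurements (triage conditions the ",
         "care transition)")
  set.seed(seed)
  n <- config$n_participants
  ids <- sprintf("P%05d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  comp <- 1 + (stats::runif(n) >= config$age_mixture$weights[1])
  age <- round(stats::rnorm(n, config$age_mixture$means[comp],
                            config$age_mixture$sds[comp]))
  age <- pmax(20, age)
  grade <- sample(names(config$grade_prevalence), n, replace = TRUE,
                  prob = config$grade_prevalence)
  band_s <- vapply(bp_bands[grade], function(b) b$sbp, numeric(2))
  band_d <- vapply(bp_bands[grade], function(b) b$dbp, numeric(2))
  true_sbp <- stats::runif(n, band_s[1, ], band_s[2, ])
  true_dbp <- stats::runif(n, band_d[1, ], band_d[2, ])

  gt <- data.frame(participant_id = ids, sex = sex, age = age,
                   grade = grade, true_sbp = round(true_sbp, 1),
                   true_dbp = round(true_dbp, 1), stringsAsFactors = FALSE)
  out <- list(measurements = NULL, labs = NULL, questionnaires = NULL)

  if ("measurements" %in% components)
    out$measurements <- generate_measurements(ids, true_sbp, true_dbp, config)

  if ("labs" %in% components) {
    flags <- sample_category_flags(n, config$category_base_rates,
                                   config$pairwise_log_odds)
    out$labs <- generate_labs(ids, sex, flags, config$abnormal_band)
    colnames(flags) <- paste0("true_", colnames(flags))
    gt <- cbind(gt, as.data.frame(flags))
  }

  if ("questionnaires" %in% components) {
    averages <- period_averages(out$measurements,
                                start_date = config$start_date)
    tri <- triage_cohort(averages, config$policy, config$thresholds)
    notified <- setNames(tri$triggered, tri$participant_id)[ids]
    notified[is.na(notified)] <- FALSE
    pre_cat <- sample(names(config$pre_category_probs), n, replace = TRUE,
                      prob = config$pre_category_probs)
    ct <- config$care_transition
    p_reg <- ifelse(pre_cat == "regular_treatment",
                    ifelse(notified, ct$stay_regular_notified,
                           ct$stay_regular_unnotified),
                    ifelse(notified, ct$to_regular_notified,
                           ct$to_regular_unnotified))
    to_regular <- stats::runif(n) < p_reg
    other <- setdiff(answer_categories(), "regular_treatment")
    fallback <- sample(other, n, replace = TRUE,
                       prob = config$pre_category_probs[other])
    post_cat <- ifelse(to_regular, "regular_treatment",
                       ifelse(pre_cat == "regular_treatment",
                              fallback, pre_cat))
    pre_ans <- stats::runif(n) < config$response_rates[["pre"]]
    post_ans <- stats::runif(n) < config$response_rates[["post"]]
    out$questionnaires <- rbind(
      data.frame(participant_id = ids, wave = "pre",
                 category = ifelse(pre_ans, pre_cat, "no_answer"),
                 stringsAsFactors = FALSE),
      data.frame(participant_id = ids, wave = "post",
                 category = ifelse(post_ans, post_cat, "no_answer"),
                 stringsAsFactors = FALSE))
    gt$notified <- as.logical(notified)
    gt$pre_category <- pre_cat
    gt$post_category <- post_cat
    gt$pre_answered <- pre_ans
    gt$post_answered <- post_ans
  }

  cohort <- structure(list(measurements = out$measurements, labs = out$labs,
                           questionnaires = out$questionnaires,
                           ground_truth = gt, config = config),
                      class = "synthetic_cohort")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in c("measurements", "labs", "questionnaires")) {
      if (!is.null(cohort[[nm]]))
        utils::write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
                         row.names = FALSE, quote = FALSE)
    }
    utils::write.csv(gt, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE, quote = FALSE)
    return(invisible(cohort))
  }
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic screening cohort: %d participants\n",
              nrow(x$ground_truth)))
  if (!is.null(x$measurements))
    cat(sprintf("  measurements: %d readings\n", nrow(x$measurements)))
  if (!is.null(x$labs))
    cat(sprintf("  labs: %d panels\n", nrow(x$labs)))
  if (!is.null(x$questionnaires))
    cat(sprintf("  questionnaires: %d responses\n", nrow(x$questionnaires)))
  invisible(x)
}

woolf_or_ci <- function(a, b, c, d, level = 0.95) {
  if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  lo <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(or = exp(lo), lower = exp(lo - z * se), upper = exp(lo + z * se))
}

#' Recover generator parameters from a synthetic cohort
#'
#' Runs the analysis stages on generated data and compares the estimates
#' against the configured latent values: (i) notification sensitivity and
#' specificity of the triage stage with respect to the latent hypertension
#' grade; (ii) pairwise odds ratios between recovered category flags versus
#' the configured couplings, with Woolf confidence intervals; (iii)
#' care-transition probabilities versus the configured ones, with exact
#' binomial confidence intervals.
#'
#' @param cohort a \code{\link{generate_cohort}} result.
#' @param level confidence level for the intervals (default 0.95).
#' @return an object of class \code{"recovery_report"}: list of data.frames
#'   \code{triage}, \code{odds_ratios}, \code{transitions}.
#' @export
recover_parameters <- function(cohort, level = 0.95) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  config <- cohort$config
  gt <- cohort$ground_truth
  out <- list()

  if (!is.null(cohort$measurements)) {
    averages <- period_averages(cohort$measurements,
                                start_date = config$start_date)
    tri <- triage_cohort(averages, config$policy, config$thresholds)
    notified <- setNames(tri$triggered, tri$participant_id)[gt$participant_id]
    notified[is.na(notified)] <- FALSE
    min_rank <- match(config$policy$min_grade, grade_levels)
    is_case <- match(gt$grade, grade_levels) >= min_rank
    ci <- function(k, m) {
      if (m == 0) return(c(NA, NA, NA))
      t <- stats::binom.test(k, m, conf.level = level)
      c(k / m, t$conf.int[1], t$conf.int[2])
    }
    se <- ci(sum(notified & is_case), sum(is_case))
    sp <- ci(sum(!notified & !is_case), sum(!is_case))
    out$triage <- data.frame(
      measure = c("sensitivity", "specificity"),
      n = c(sum(is_case), sum(!is_case)),
      estimate = c(se[1], sp[1]), lower = c(se[2], sp[2]),
      upper = c(se[3], sp[3]),
      policy = config$policy$label, stringsAsFactors = FALSE)
  }

  if (!is.null(cohort$labs)) {
    flags <- categorize_panels(cohort$labs)
    cats <- category_names()
    rows <- list()
    for (i in seq_along(cats)) for (j in seq_along(cats)) {
      if (j <= i) next
      x <- flags[[cats[i]]]; y <- flags[[cats[j]]]
      est <- woolf_or_ci(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y),
                         level)
      rows[[length(rows) + 1]] <- data.frame(
        pair = paste(cats[i], cats[j], sep = ":"),
        configured_or = exp(config$pairwise_log_odds[cats[i], cats[j]]),
        estimate = est[["or"]], lower = est[["lower"]],
        upper = est[["upper"]], stringsAsFactors = FALSE)
    }
    out$odds_ratios <- do.call(rbind, rows)
  }

  if (!is.null(cohort$questionnaires) && !is.null(gt$post_category)) {
    ct <- config$care_transition
    cell <- function(pre_regular, notified_state, configured) {
      sel <- (gt$pre_category == "regular_treatment") == pre_regular &
        gt$notified == notified_state
      k <- sum(gt$post_category[sel] == "regular_treatment")
      m <- sum(sel)
      est <- if (m > 0) {
        t <- stats::binom.test(k, m, conf.level = level)
        c(k / m, t$conf.int)
      } else c(NA, NA, NA)
      data.frame(transition = paste0(
        if (pre_regular) "stay_regular_" else "to_regular_",
        if (notified_state) "notified" else "unnotified"),
        n = m, configured = configured, estimate = est[1],
        lower = est[2], upper = est[3], stringsAsFactors = FALSE)
    }
    out$transitions <- rbind(
      cell(FALSE, TRUE, ct$to_regular_notified),
      cell(FALSE, FALSE, ct$to_regular_unnotified),
      cell(TRUE, TRUE, ct$stay_regular_notified),
      cell(TRUE, FALSE, ct$stay_regular_unnotified))
  }
  structure(out, class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery from the synthetic cohort\n")
  for (nm in names(x)) {
    cat("\n--", nm, "--\n")
    print(x[[nm]], row.names = FALSE, digits = 4)
  }
  invisible(x)
}
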