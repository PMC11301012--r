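#' Hypertension grade thresholds
#'
#' Grade bands in the JSH2009 style: Grade I >= 140/90, Grade II >= 160/100,
#' Grade III >= 180/110 mmHg, where a grade is met when the systolic OR the
#' diastolic criterion is met. Comparisons use \code{>=} at the band edges.
#'
#' @param grade1 numeric length-2 \code{c(sbp, dbp)} for Grade I.
#' @param grade2 numeric length-2 for Grade II.
#' @param grade3 numeric length-2 for Grade III.
#' @return an object of class \code{"grade_thresholds"}.
#' @export
grade_thresholds <- function(grade1 = c(sbp = 140, dbp = 90),
                             grade2 = c(sbp = 160, dbp = 100),
                             grade3 = c(sbp = 180, dbp = 110)) {
  th <- rbind(grade1 = grade1, grade2 = grade2, grade3 = grade3)
  colnames(th) <- c("sbp", "dbp")
  if (any(diff(th[, "sbp"]) <= 0) || any(diff(th[, "dbp"]) <= 0))
    stop("grade thresholds must be strictly increasing across grades")
  structure(list(table = th), class = "grade_thresholds")
}

#' Urgent-notification policy
#'
#' Which hypertension grade triggers an urgent notification, and how many
#' retained measurements a period average must be based on to be eligible.
#' Averages over two or fewer readings never trigger a notification under
#' the default \code{min_measurements = 3}.
#'
#' @param label \code{"grade3_only"} (notify on Grade III or higher) or
#'   \code{"grade2_plus"} (notify on Grade II or higher). The forms
#'   \code{"grade3only"}/\code{"grade2plus"} and upper-case variants are
#'   accepted.
#' @param min_measurements minimum number of retained readings behind an
#'   eligible period average (default 3).
#' @return an object of class \code{"notification_policy"}.
#' @export
notification_policy <- function(label = c("grade3_only", "grade2_plus"),
                                min_measurements = 3L) {
  lab <- tolower(gsub("[^a-z0-9]", "", tolower(as.character(label[1]))))
  lab <- switch(lab,
                grade3only = , gradeiiionly = "grade3_only",
                grade2plus = , gradeiiplus = "grade2_plus",
                stop("unknown policy label: ", label[1]))
  min_measurements <- as.integer(min_measurements)
  if (is.na(min_measurements) || min_measurements < 1)
    stop("min_measurements must be an integer >= 1")
  structure(list(label = lab,
                 min_grade = if (lab == "grade3_only") "grade3" else "grade2",
                 min_measurements = min_measurements),
            class = "notification_policy")
}

#' Policy in force on a given date
#'
#' Convenience mapping of the programme's two policy phases: Grade II or
#' higher triggered notifications before the revision date, Grade III only
#' from the revision date onwards (default 2014-07-01).
#'
#' @param date a \code{Date} (or coercible).
#' @param revision_date the date the stricter criterion took effect.
#' @param min_measurements passed to \code{\link{notification_policy}}.
#' @return a \code{notification_policy}.
#' @export
policy_for_date <- function(date, revision_date = as.Date("2014-07-01"),
                            min_measurements = 3L) {
  lab <- if (as.Date(date) < as.Date(revision_date)) "grade2_plus" else "grade3_only"
  notification_policy(lab, min_measurements)
}

grade_levels <- c("none", "grade1", "grade2", "grade3")

#' Classify a blood pressure average into a hypertension grade
#'
#' Returns the highest grade whose systolic or diastolic threshold is met;
#' below Grade I returns \code{"none"}. Vectorised over \code{sbp}/\code{dbp}.
#'
#' @param sbp systolic pressure, mmHg.
#' @param dbp diastolic pressure, mmHg.
#' @param thresholds a \code{\link{grade_thresholds}} object.
#' @return character vector in \code{c("none","grade1","grade2","grade3")}.
#' @export
#' @examples
#' grade_bp(185, 95)    # grade3 via the systolic criterion
#' grade_bp(160, 100)   # grade2 at the band edge
grade_bp <- function(sbp, dbp, thresholds = grade_thresholds()) {
  if (any(is.na(sbp)) || any(is.na(dbp)) || any(sbp <= 0) || any(dbp <= 0))
    stop("grade_bp requires positive, non-missing sbp and dbp")
  th <- thresholds$table
  g <- rep("none", length(sbp))
  for (i in seq_len(nrow(th)))
    g[sbp >= th[i, "sbp"] | dbp >= th[i, "dbp"]] <- rownames(th)[i]
  g
}

#' Evaluate the urgent-notification criteria for one participant
#'
#' A period qualifies when its average is based on at least
#' \code{policy$min_measurements} retained readings and its grade meets the
#' policy's minimum grade. The participant is notified when any period
#' qualifies; the reported grade is the maximum over all eligible periods
#' (those meeting the measurement-count requirement).
#'
#' @param averages data.frame of one participant's period averages as
#'   produced by \code{\link{period_averages}}.
#' @param policy a \code{\link{notification_policy}}.
#' @param thresholds a \code{\link{grade_thresholds}} object.
#' @return an object of class \code{"triage_result"}: a list with
#'   \code{participant_id}, \code{triggered}, \code{grade},
#'   \code{qualifying_periods}, \code{policy} and a \code{reasons} audit
#'   trail (one line per period).
#' @export
evaluate_notification <- function(averages,
                                  policy = notification_policy("grade3_only"),
                                  thresholds = grade_thresholds()) {
  stopifnot(inherits(policy, "notification_policy"))
  id <- unique(averages$participant_id)
  if (length(id) != 1)
    stop("evaluate_notification expects one participant's averages")
  reasons <- character(0)
  grades <- setNames(rep(NA_character_, length(bp_periods)), bp_periods)
  eligible <- setNames(rep(FALSE, length(bp_periods)), bp_periods)
  for (p in bp_periods) {
    row <- averages[averages$period == p, , drop = FALSE]
    if (nrow(row) == 0 || row$n_used[1] == 0) {
      reasons <- c(reasons, sprintf("%s: no retained measurements", p))
      next
    }
    g <- grade_bp(row$mean_sbp[1], row$mean_dbp[1], thresholds)
    grades[p] <- g
    if (row$n_used[1] < policy$min_measurements) {
      reasons <- c(reasons, sprintf(
        "%s: %s on %d measurement(s) < %d required; ineligible",
        p, g, row$n_used[1], policy$min_measurements))
    } else {
      eligible[p] <- TRUE
      reasons <- c(reasons, sprintf(
        "%s: %s on %d measurement(s) (%.1f/%.1f mmHg)",
        p, g, row$n_used[1], row$mean_sbp[1], row$mean_dbp[1]))
    }
  }
  min_rank <- match(policy$min_grade, grade_levels)
  qualifies <- eligible & !is.na(grades) &
    match(grades, grade_levels) >= min_rank
  triggered <- any(qualifies)
  grade <- if (any(eligible)) {
    grade_levels[max(match(grades[eligible], grade_levels))]
  } else NA_character_
  if (!any(eligible))
    reasons <- c(reasons, "no eligible period")
  reasons <- c(reasons, if (triggered) {
    sprintf("notify: %s meets policy %s in period(s) %s",
            grade, policy$label,
            paste(names(qualifies)[qualifies], collapse = ", "))
  } else "no notification")
  structure(list(participant_id = id, triggered = triggered, grade = grade,
                 qualifying_periods = names(qualifies)[qualifies],
                 policy = policy$label, reasons = reasons),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("Urgent-notification triage for participant %s\n",
              x$participant_id))
  cat(sprintf("  policy: %s; triggered: %s; grade: %s\n", x$policy,
              x$triggered, ifelse(is.na(x$grade), "-", x$grade)))
  if (length(x$qualifying_periods))
    cat("  qualifying periods:", paste(x$qualifying_periods, collapse = ", "),
        "\n")
  cat(paste0("  ", x$reasons, collapse = "\n"), "\n")
  invisible(x)
}

#' Triage a whole cohort of period averages
#'
#' @param averages data.frame of period averages for many participants.
#' @param policy a \code{\link{notification_policy}}.
#' @param thresholds a \code{\link{grade_thresholds}} object.
#' @return data.frame with one row per participant:
#'   \code{participant_id,triggered,grade,qualifying_periods,policy};
#'   \code{qualifying_periods} is a \code{;}-separated string. The full
#'   \code{triage_result} objects are attached as attribute
#'   \code{"results"}.
#' @export
triage_cohort <- function(averages,
                          policy = notification_policy("grade3_only"),
                          thresholds = grade_thresholds()) {
  ids <- unique(averages$participant_id)
  results <- lapply(ids, function(id)
    evaluate_notification(averages[averages$participant_id == id, ,
                                   drop = FALSE], policy, thresholds))
  out <- data.frame(
    participant_id = ids,
    triggered = vapply(results, `[[`, logical(1), "triggered"),
    grade = vapply(results, `[[`, character(1), "grade"),
    qualifying_periods = vapply(results, function(r)
      paste(r$qualifying_periods, collapse = ";"), character(1)),
    policy = policy$label, stringsAsFactors = FALSE)
  attr(out, "results") <- setNames(results, ids)
  out
}

#' Compose an urgent-notification letter
#'
#' Renders the letter sent to a notified participant: the hypertension grade
#' statement, the period averages the decision was based on, one line per
#' abnormal laboratory category (when category flags are supplied), and a
#' fixed care recommendation. Rendering is deterministic: identical inputs
#' produce byte-identical letters.
#'
#' @param result a triggered \code{\link{evaluate_notification}} result.
#' @param flags optional named logical vector (or one-row data.frame) of the
#'   five abnormality categories \code{blood_sugar}, \code{renal},
#'   \code{lipid}, \code{hematological}, \code{liver}.
#' @param averages the participant's period averages (for the value lines).
#' @return the letter as a single character string.
#' @export
compose_letter <- function(result, flags = NULL, averages = NULL) {
  stopifnot(inherits(result, "triage_result"))
  if (!isTRUE(result$triggered))
    stop("compose_letter requires a triggered triage result")
  grade_txt <- c(grade2 = "Grade II hypertension (>= 160/100 mmHg)",
                 grade3 = "Grade III hypertension (>= 180/110 mmHg)")
  lines <- c(
    sprintf("URGENT NOTIFICATION OF HOME BLOOD PRESSURE RESULTS"),
    sprintf("Participant: %s", result$participant_id),
    "",
    sprintf("Your 14-day home blood pressure averages meet the criteria for %s.",
            if (result$grade %in% names(grade_txt))
              grade_txt[[result$grade]] else result$grade),
    sprintf("Qualifying period(s): %s.",
            paste(result$qualifying_periods, collapse = ", ")))
  if (!is.null(averages)) {
    av <- averages[averages$n_used > 0, , drop = FALSE]
    if (nrow(av) > 0)
      lines <- c(lines, "", "Average home blood pressure:",
                 sprintf("  %-8s %5.1f/%5.1f mmHg (n = %d)",
                         av$period, av$mean_sbp, av$mean_dbp, av$n_used))
  }
  if (!is.null(flags)) {
    fl <- unlist(flags[category_names()])
    if (any(fl)) {
      cat_txt <- c(blood_sugar = "blood sugar (glucose metabolism)",
                   renal = "renal function (creatinine / blood urea nitrogen)",
                   lipid = "serum lipid levels",
                   hematological = "blood cell counts or morphology",
                   liver = "liver function (AST / ALT)")
      lines <- c(lines, "",
                 "Your health examination also showed abnormal values in:",
                 sprintf("  - %s", cat_txt[names(fl)[fl]]))
    }
  }
  lines <- c(lines, "",
             paste("We recommend that you consult a physician promptly,",
                   "taking this letter with you."))
  paste(lines, collapse = "\n")
}
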