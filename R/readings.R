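#' Time-of-day periods for home blood pressure monitoring
#'
#' The 14-day home monitoring protocol divides each logical day into three
#' clock windows: morning 04:00--11:00, midday 11:00--16:00 and evening
#' 16:00--04:00 of the next calendar day. Intervals are half-open on the
#' right so the three windows partition the 24-hour clock exactly; a reading
#' taken between midnight and 04:00 belongs to the evening period of the
#' previous calendar day.
#'
#' @param timestamp character vector of timestamps, ISO-8601 local time
#'   (\code{"YYYY-MM-DDTHH:MM"}; a space separator and trailing seconds are
#'   accepted).
#' @return a data.frame with columns \code{period} (\code{"morning"},
#'   \code{"midday"} or \code{"evening"}) and \code{logical_day}
#'   (\code{Date}): the monitoring day the reading is attributed to.
#' @export
#' @examples
#' assign_period("2014-03-01T06:30")  # morning of 2014-03-01
#' assign_period("2014-03-02T02:00")  # evening of 2014-03-01
assign_period <- function(timestamp) {
  ts <- parse_timestamp(timestamp)
  if (anyNA(ts$minute)) {
    bad <- which(is.na(ts$minute))
    stop("unparseable timestamp(s) at position(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "")
  }
  m <- ts$minute
  period <- ifelse(m < 4 * 60, "evening",
            ifelse(m < 11 * 60, "morning",
            ifelse(m < 16 * 60, "midday", "evening")))
  logical_day <- ts$date - (m < 4 * 60)
  data.frame(period = period, logical_day = logical_day,
             stringsAsFactors = FALSE)
}

bp_periods <- c("morning", "midday", "evening")

check_measurements <- function(measurements) {
  required <- c("participant_id", "timestamp", "sbp", "dbp")
  missing <- setdiff(required, names(measurements))
  if (length(missing) > 0)
    stop("measurements lack required column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(!(measurements$sbp > measurements$dbp & measurements$dbp > 0))
  if (length(bad) > 0)
    stop("invalid blood pressure rows (need sbp > dbp > 0): rows ",
         paste(utils::head(bad, 5L), collapse = ", "))
  invisible(measurements)
}

#' Keep the first reading per day-period cell
#'
#' When a participant measures more than once within the same time period of
#' the same monitoring day, only the first (earliest) measurement is used.
#' Duplicate identical timestamps in a cell keep the first row by input
#' order, with a warning.
#'
#' @param measurements data.frame with columns \code{participant_id},
#'   \code{timestamp}, \code{sbp}, \code{dbp}; all rows must belong to a
#'   single participant.
#' @return the surviving rows in chronological order, with the input columns
#'   plus \code{period} and \code{logical_day}.
#' @export
dedup_first_per_period <- function(measurements) {
  check_measurements(measurements)
  if (nrow(measurements) == 0) {
    out <- measurements
    out$period <- character(0)
    out$logical_day <- as.Date(character(0))
    return(out)
  }
  if (length(unique(measurements$participant_id)) > 1)
    stop("dedup_first_per_period expects a single participant's stream")
  pa <- assign_period(measurements$timestamp)
  ts <- parse_timestamp(measurements$timestamp)
  key <- paste(pa$logical_day, pa$period)
  ord <- order(as.numeric(ts$date) * 1440 + ts$minute, seq_len(nrow(measurements)))
  keep <- ord[!duplicated(key[ord])]
  dup_ts <- any(duplicated(paste(key, measurements$timestamp)))
  if (dup_ts)
    warning("duplicate identical timestamps within a day-period cell; ",
            "keeping first by input order")
  keep <- sort(keep)
  out <- measurements[keep, , drop = FALSE]
  out$period <- pa$period[keep]
  out$logical_day <- pa$logical_day[keep]
  ots <- parse_timestamp(out$timestamp)
  out <- out[order(as.numeric(ots$date) * 1440 + ots$minute), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-period 14-day averages of home blood pressure
#'
#' Reduces one or more participants' measurement streams to the arithmetic
#' mean systolic and diastolic pressure per time-of-day period, after keeping
#' only the first reading in each day-period cell. Periods without any
#' retained reading are reported with \code{n_used = 0} and \code{NA} means.
#'
#' @param measurements data.frame with columns \code{participant_id},
#'   \code{timestamp}, \code{sbp}, \code{dbp}.
#' @param start_date optional \code{Date} (scalar, or named vector by
#'   participant id): start of the 14-day monitoring window. Readings whose
#'   logical day falls outside \code{[start_date, start_date + window_days)}
#'   are dropped with a warning.
#' @param window_days length of the monitoring window in days (default 14).
#' @param dedup apply \code{dedup_first_per_period} first (default TRUE).
#'   Set to FALSE only for streams already reduced to one reading per cell.
#' @return data.frame with one row per participant and period:
#'   \code{participant_id}, \code{period}, \code{n_used}, \code{mean_sbp},
#'   \code{mean_dbp}.
#' @export
period_averages <- function(measurements, start_date = NULL,
                            window_days = 14, dedup = TRUE) {
  check_measurements(measurements)
  ids <- unique(measurements$participant_id)
  if (length(ids) == 0) ids <- character(0)
  res <- lapply(ids, function(id) {
    one <- measurements[measurements$participant_id == id, , drop = FALSE]
    one <- if (dedup) dedup_first_per_period(one) else {
      pa <- assign_period(one$timestamp)
      one$period <- pa$period
      one$logical_day <- pa$logical_day
      one
    }
    if (!is.null(start_date)) {
      s <- if (!is.null(names(start_date))) start_date[[id]] else start_date
      s <- as.Date(s)
      inside <- one$logical_day >= s & one$logical_day < s + window_days
      if (any(!inside))
        warning(sum(!inside), " reading(s) outside the ", window_days,
                "-day window for participant ", id, " dropped")
      one <- one[inside, , drop = FALSE]
    }
    out <- data.frame(participant_id = id, period = bp_periods,
                      n_used = 0L, mean_sbp = NA_real_, mean_dbp = NA_real_,
                      stringsAsFactors = FALSE)
    for (p in bp_periods) {
      sel <- one$period == p
      if (any(sel)) {
        i <- match(p, bp_periods)
        out$n_used[i] <- sum(sel)
        out$mean_sbp[i] <- mean(one$sbp[sel])
        out$mean_dbp[i] <- mean(one$dbp[sel])
      }
    }
    out
  })
  if (length(res) == 0)
    return(data.frame(participant_id = character(0), period = character(0),
                      n_used = integer(0), mean_sbp = numeric(0),
                      mean_dbp = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read a measurements CSV
#'
#' Expects the header \code{participant_id,timestamp,sbp,dbp} with ISO-8601
#' local timestamps, one row per reading.
#'
#' @param path file path.
#' @return data.frame of measurements.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  check_measurements(df)
  df
}
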