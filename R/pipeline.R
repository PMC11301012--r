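#' Validate pipeline input files
#'
#' Schema, type and referential checks on the three input CSVs. Structural
#' problems (missing required columns, impossible blood pressure rows,
#' unparseable timestamps, duplicate questionnaire responses) are blocking
#' errors; cross-file issues (a lab panel or questionnaire row whose
#' participant has no measurements) are non-blocking warnings and the rows
#' are retained.
#'
#' @param measurements,labs,questionnaires file paths (any may be NULL).
#' @return an object of class \code{"validation_report"}: a data.frame with
#'   columns \code{severity} (\code{"error"}/\code{"warning"}),
#'   \code{file}, \code{message}. Zero rows means a clean bill.
#' @export
validate_inputs <- function(measurements = NULL, labs = NULL,
                            questionnaires = NULL) {
  issues <- list()
  add <- function(severity, file, message)
    issues[[length(issues) + 1]] <<- data.frame(
      severity = severity, file = file, message = message,
      stringsAsFactors = FALSE)
  meas_ids <- NULL

  if (!is.null(measurements)) {
    df <- utils::read.csv(measurements, stringsAsFactors = FALSE,
                          colClasses = "character")
    required <- c("participant_id", "timestamp", "sbp", "dbp")
    miss <- setdiff(required, names(df))
    if (length(miss) > 0) {
      add("error", measurements,
          paste("missing required column(s):", paste(miss, collapse = ", ")))
    } else {
      sbp <- suppressWarnings(as.numeric(df$sbp))
      dbp <- suppressWarnings(as.numeric(df$dbp))
      bad <- which(is.na(sbp) | is.na(dbp) | !(sbp > dbp & dbp > 0))
      if (length(bad) > 0)
        add("error", measurements,
            paste0("invalid blood pressure (need sbp > dbp > 0) in row(s): ",
                   paste(utils::head(bad, 10), collapse = ", ")))
      ts <- parse_timestamp(df$timestamp)
      badts <- which(is.na(ts$minute))
      if (length(badts) > 0)
        add("error", measurements,
            paste0("unparseable timestamp in row(s): ",
                   paste(utils::head(badts, 10), collapse = ", ")))
      meas_ids <- unique(df$participant_id)
    }
  }

  if (!is.null(labs)) {
    df <- try(read_labs(labs), silent = TRUE)
    if (inherits(df, "try-error")) {
      add("error", labs, conditionMessage(attr(df, "condition")))
    } else {
      if (!all(df$sex %in% c("male", "female")))
        add("error", labs, "sex must be 'male' or 'female'")
      if (!is.null(meas_ids)) {
        orphan <- setdiff(df$participant_id, meas_ids)
        if (length(orphan) > 0)
          add("warning", labs,
              paste0(length(orphan), " lab row(s) with no measurement ",
                     "stream (rows retained): ",
                     paste(utils::head(orphan, 5), collapse = ", ")))
      }
    }
  }

  if (!is.null(questionnaires)) {
    df <- utils::read.csv(questionnaires, stringsAsFactors = FALSE,
                          colClasses = "character")
    ok <- try(check_responses(df), silent = TRUE)
    if (inherits(ok, "try-error")) {
      add("error", questionnaires, conditionMessage(attr(ok, "condition")))
    } else if (!is.null(meas_ids)) {
      orphan <- setdiff(df$participant_id, meas_ids)
      if (length(orphan) > 0)
        add("warning", questionnaires,
            paste0(length(orphan), " questionnaire row(s) with no ",
                   "measurement stream (rows retained)"))
    }
  }

  out <- if (length(issues) > 0) do.call(rbind, issues)
  else data.frame(severity = character(0), file = character(0),
                  message = character(0), stringsAsFactors = FALSE)
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("Input validation: no issues\n")
  } else {
    cat(sprintf("Input validation: %d error(s), %d warning(s)\n",
                sum(x$severity == "error"), sum(x$severity == "warning")))
    cat(sprintf("  [%s] %s: %s\n", x$severity, basename(x$file), x$message),
        sep = "")
  }
  invisible(x)
}

default_run_config <- function() {
  list(policy = "grade3_only", min_measurements = 3, alpha_family = 0.05,
       fisher_threshold = 5, window_days = 14, start_date = NULL,
       thresholds = NULL, seed = 1L)
}

build_thresholds <- function(cfg) {
  th <- cfg$thresholds
  if (is.null(th)) return(grade_thresholds())
  grade_thresholds(
    grade1 = c(sbp = th$grade1$sbp %||% 140, dbp = th$grade1$dbp %||% 90),
    grade2 = c(sbp = th$grade2$sbp %||% 160, dbp = th$grade2$dbp %||% 100),
    grade3 = c(sbp = th$grade3$sbp %||% 180, dbp = th$grade3$dbp %||% 110))
}

#' Run the screening pipeline end to end
#'
#' Executes the stages readings -> triage -> lab flags -> association ->
#' behaviour on either supplied input CSVs or a simulated cohort, persisting
#' every intermediate artifact as CSV under \code{out_dir} so later stages
#' can be re-run and audited independently. Letters for notified
#' participants are written as one UTF-8 text file each under
#' \code{letters/}; a machine-readable \code{manifest.json} records the
#' package version, a config fingerprint, the seed and per-stage row
#' counts; \code{audit.log} records each participant's triage decision
#' path. Outputs are reproducible from config + seed.
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Exactly one of \code{input} (list with paths \code{measurements},
#'   \code{labs}, \code{questionnaires}) or \code{simulate} (arguments for
#'   \code{\link{synthetic_config}}) must be present. Optional keys:
#'   \code{policy} (\code{"grade3_only"}/\code{"grade2_plus"}),
#'   \code{min_measurements}, \code{alpha_family}, \code{fisher_threshold},
#'   \code{window_days}, \code{start_date}, \code{thresholds} (nested lists
#'   \code{grade1}/\code{grade2}/\code{grade3} with \code{sbp}/\code{dbp}),
#'   \code{seed}.
#' @param out_dir output directory (created if needed).
#' @param seed overrides \code{config$seed}.
#' @return (invisibly) a list with the stage outputs: \code{averages},
#'   \code{triage}, \code{flags}, \code{association}, \code{behavior},
#'   \code{validation}, \code{manifest}.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  if (!xor(is.null(cfg$input), is.null(cfg$simulate)))
    stop("config must contain exactly one of 'input' or 'simulate'")
  seed <- as.integer(seed %||% cfg$seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg_string <- yaml::as.yaml(config)

  policy <- notification_policy(cfg$policy, cfg$min_measurements)
  thresholds <- build_thresholds(cfg)

  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$policy <- policy
    sim_args$thresholds <- thresholds
    if (!is.null(sim_args$start_date))
      sim_args$start_date <- as.Date(sim_args$start_date)
    sim_cfg <- do.call(synthetic_config, sim_args)
    input_dir <- file.path(out_dir, "inputs")
    generate_cohort(sim_cfg, seed = seed, dir = input_dir)
    paths <- list(measurements = file.path(input_dir, "measurements.csv"),
                  labs = file.path(input_dir, "labs.csv"),
                  questionnaires = file.path(input_dir, "questionnaires.csv"))
    if (is.null(cfg$start_date)) cfg$start_date <- sim_cfg$start_date
  } else {
    paths <- cfg$input
  }

  validation <- validate_inputs(paths$measurements, paths$labs,
                                paths$questionnaires)
  utils::write.csv(validation, file.path(out_dir, "validation.csv"),
                   row.names = FALSE)
  if (any(validation$severity == "error")) {
    print(validation)
    stop("blocking validation error(s); see validation.csv")
  }

  measurements <- read_measurements(paths$measurements)
  start_date <- if (!is.null(cfg$start_date)) as.Date(cfg$start_date)
  averages <- suppressWarnings(
    period_averages(measurements, start_date = start_date,
                    window_days = cfg$window_days))
  utils::write.csv(averages, file.path(out_dir, "period_averages.csv"),
                   row.names = FALSE, quote = FALSE)

  triage <- triage_cohort(averages, policy, thresholds)
  utils::write.csv(triage, file.path(out_dir, "triage.csv"),
                   row.names = FALSE, quote = FALSE)
  results <- attr(triage, "results")
  audit <- unlist(lapply(results, function(r)
    c(sprintf("participant %s: data received, %s", r$participant_id,
              if (r$triggered) "notification issued" else "no notification"),
      paste0("  ", r$reasons))))
  writeLines(audit, file.path(out_dir, "audit.log"))

  flags <- NULL
  if (!is.null(paths$labs)) {
    labs <- read_labs(paths$labs)
    flags <- categorize_panels(labs)
    utils::write.csv(flags, file.path(out_dir, "flags.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  letters_dir <- file.path(out_dir, "letters")
  if (!dir.exists(letters_dir)) dir.create(letters_dir)
  for (id in triage$participant_id[triage$triggered]) {
    fl <- if (!is.null(flags))
      flags[flags$participant_id == id, , drop = FALSE]
    if (!is.null(fl) && nrow(fl) == 0) fl <- NULL
    letter <- compose_letter(
      results[[id]], flags = fl,
      averages = averages[averages$participant_id == id, , drop = FALSE])
    writeLines(letter, file.path(letters_dir, paste0(id, ".txt")))
  }

  association <- NULL
  if (!is.null(flags)) {
    notified_flags <- flags[flags$participant_id %in%
                              triage$participant_id[triage$triggered], ,
                            drop = FALSE]
    if (nrow(notified_flags) >= 2) {
      association <- pairwise_association(notified_flags, cfg$alpha_family,
                                          fisher_threshold = cfg$fisher_threshold)
      utils::write.csv(as.data.frame(association),
                       file.path(out_dir, "association.csv"),
                       row.names = FALSE, quote = FALSE)
      writeLines(utils::capture.output(print(association)),
                 file.path(out_dir, "association.txt"))
    }
  }

  behavior <- NULL
  if (!is.null(paths$questionnaires)) {
    responses <- utils::read.csv(paths$questionnaires,
                                 stringsAsFactors = FALSE,
                                 colClasses = "character")
    behavior <- behavior_report(responses)
    writeLines(utils::capture.output(print(behavior)),
               file.path(out_dir, "behavior.txt"))
  }

  manifest <- list(
    package = "hbpalert",
    version = as.character(utils::packageVersion("hbpalert")),
    seed = seed,
    config_hash = config_hash(cfg_string),
    policy = policy$label,
    rows = list(
      measurements = nrow(measurements),
      participants = length(unique(measurements$participant_id)),
      period_averages = nrow(averages),
      triaged = nrow(triage),
      notified = sum(triage$triggered),
      flagged = if (!is.null(flags)) nrow(flags) else 0L,
      association_pairs = if (!is.null(association)) nrow(association) else 0L,
      responses = if (!is.null(behavior))
        sum(behavior$pre$counts) + sum(behavior$post$counts) else 0L))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(averages = averages, triage = triage, flags = flags,
                 association = association, behavior = behavior,
                 validation = validation, manifest = manifest))
}
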