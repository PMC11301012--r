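#' Reference ranges for the screening blood panel
#'
#' The clinical reference intervals used to flag laboratory values, as
#' applied in the community screening programme the package models. Bounds
#' are inclusive on both ends: a value exactly at a bound is normal. Where a
#' range is sex-specific, one row per sex is given; otherwise the row applies
#' to both sexes. CRP has no lower limit of clinical interest and its lower
#' bound is 0. Lipid values are not part of this registry: lipid abnormality
#' enters the pipeline as a precomputed boolean column (see
#' \code{\link{categorize}}).
#'
#' A copy of the default registry ships as
#' \code{system.file("extdata", "reference_ranges.csv", package =
#' "hbpalert")}; pass an edited copy via \code{path} to override.
#'
#' @param path optional CSV with columns
#'   \code{analyte,sex,low,high,unit} replacing the built-in registry.
#' @return data.frame with columns \code{analyte}, \code{sex}
#'   (\code{"male"}, \code{"female"} or \code{"both"}), \code{low},
#'   \code{high}, \code{unit}.
#' @export
reference_ranges <- function(path = NULL) {
  if (!is.null(path)) {
    out <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("analyte", "sex", "low", "high") %in% names(out)),
              all(out$low <= out$high))
    return(out)
  }
  rr <- rbind(
    c("crp",         "both",   "0",    "0.30", "mg/dL"),
    c("hemoglobin",  "male",   "13.5", "17.5", "g/dL"),
    c("hemoglobin",  "female", "11.5", "15.0", "g/dL"),
    c("platelets",   "both",   "14.0", "34.0", "10^4/uL"),
    c("leukocytes",  "both",   "3300", "9000", "/uL"),
    c("blood_sugar", "both",   "70",   "109",  "mg/dL"),
    c("ast",         "both",   "10",   "40",   "IU/L"),
    c("alt",         "both",   "5",    "45",   "IU/L"),
    c("creatinine",  "male",   "0.61", "1.04", "mg/dL"),
    c("creatinine",  "female", "0.47", "0.79", "mg/dL"),
    c("bun",         "both",   "8.0",  "20.0", "mg/dL"),
    c("uric_acid",   "male",   "3.8",  "7.0",  "mg/dL"),
    c("uric_acid",   "female", "2.5",  "7.0",  "mg/dL"),
    c("sodium",      "both",   "137",  "147",  "mEq/L"))
  out <- data.frame(analyte = rr[, 1], sex = rr[, 2],
                    low = as.numeric(rr[, 3]), high = as.numeric(rr[, 4]),
                    unit = rr[, 5], stringsAsFactors = FALSE)
  stopifnot(all(out$low <= out$high))
  out
}

category_names <- function() {
  c("blood_sugar", "renal", "lipid", "hematological", "liver")
}

#' Mapping of analytes to abnormality categories
#'
#' Which flagged analytes roll up into each of the five abnormality
#' categories used in the co-occurrence analysis. Uric acid, sodium and CRP
#' are flagged individually but map to no category by default; lipid is a
#' pass-through boolean. The mapping is an argument everywhere it is used so
#' alternatives are one edit away.
#'
#' @return named list of character vectors of analyte names; the
#'   \code{hematological} entry additionally includes the cell-morphology
#'   rule (see \code{\link{flag_abnormal_cells}}).
#' @export
category_mapping <- function() {
  list(blood_sugar = "blood_sugar",
       renal = c("creatinine", "bun"),
       liver = c("ast", "alt"),
       hematological = c("hemoglobin", "platelets", "leukocytes"))
}

#' Flag one analyte value against its reference range
#'
#' @param analyte analyte name as in \code{\link{reference_ranges}}.
#' @param value numeric value(s); \code{NA} yields \code{"missing"} (absence
#'   is never treated as normal).
#' @param sex \code{"male"} or \code{"female"}; used where the range is
#'   sex-specific. Recycled against \code{value}.
#' @param ranges a reference-range registry data.frame.
#' @return character vector in \code{c("low","normal","high","missing")}.
#' @export
#' @examples
#' flag_analyte("creatinine", 1.20, "male")   # "high"
#' flag_analyte("blood_sugar", 109, "female") # "normal": bounds inclusive
flag_analyte <- function(analyte, value, sex, ranges = reference_ranges()) {
  rows <- ranges[ranges$analyte == analyte, , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown analyte: ", analyte)
  n <- max(length(value), length(sex))
  value <- rep_len(value, n)
  sex <- rep_len(sex, n)
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  idx <- if (nrow(rows) == 1 && rows$sex[1] == "both")
    rep(1L, n) else match(sex, rows$sex)
  if (anyNA(idx))
    stop("no unique reference range for ", analyte)
  low <- rows$low[idx]; high <- rows$high[idx]
  ifelse(is.na(value), "missing",
         ifelse(value < low, "low", ifelse(value > high, "high", "normal")))
}

#' Blood-cell morphology abnormality rule
#'
#' True when immature blast cells are present, multiple atypical cells are
#' present, or more than 30 erythroblasts are seen per 200 nucleated cells
#' (strictly more: 30 itself is not abnormal).
#'
#' @param blast_cells_present logical.
#' @param multiple_atypical_cells logical.
#' @param erythroblasts_per_200 integer count, per 200 nucleated cells.
#' @return logical vector.
#' @export
flag_abnormal_cells <- function(blast_cells_present, multiple_atypical_cells,
                                erythroblasts_per_200) {
  as.logical(blast_cells_present) | as.logical(multiple_atypical_cells) |
    (erythroblasts_per_200 > 30)
}

#' Roll a laboratory panel up into the five abnormality categories
#'
#' Flags every registry analyte against its reference range and reduces the
#' flags to the five categories used in the co-occurrence analysis:
#' blood sugar, renal (creatinine or BUN), lipid (pass-through boolean),
#' hematological (hemoglobin, platelets, leukocytes or the cell-morphology
#' rule) and liver (AST or ALT). Missing analytes contribute \code{FALSE}
#' to their category, with a note.
#'
#' @param panel one participant's panel: a list or one-row data.frame with
#'   \code{sex}, the analyte columns, the morphology fields
#'   (\code{blast_cells}, \code{atypical_cells},
#'   \code{erythroblasts_per_200}) and \code{lipid_abnormal}.
#' @param ranges reference-range registry.
#' @param mapping analyte-to-category mapping, see
#'   \code{\link{category_mapping}}.
#' @param note function called with a message for each missing analyte
#'   (default \code{message}); use \code{function(...) NULL} to silence.
#' @return named logical vector over the five categories.
#' @export
categorize <- function(panel, ranges = reference_ranges(),
                       mapping = category_mapping(), note = message) {
  panel <- as.list(panel)
  abn <- function(analyte) {
    v <- panel[[analyte]]
    if (is.null(v) || is.na(v)) {
      note("analyte '", analyte, "' missing; contributes no abnormality")
      return(FALSE)
    }
    flag_analyte(analyte, v, panel$sex, ranges) %in% c("low", "high")
  }
  flags <- c(
    blood_sugar = any(vapply(mapping$blood_sugar, abn, logical(1))),
    renal = any(vapply(mapping$renal, abn, logical(1))),
    lipid = isTRUE(as.logical(panel$lipid_abnormal)),
    hematological = any(vapply(mapping$hematological, abn, logical(1))) ||
      isTRUE(flag_abnormal_cells(panel$blast_cells %||% FALSE,
                                 panel$atypical_cells %||% FALSE,
                                 panel$erythroblasts_per_200 %||% 0L)),
    liver = any(vapply(mapping$liver, abn, logical(1))))
  flags[category_names()]
}

#' Categorise a whole labs table
#'
#' @param labs data.frame in the labs CSV schema (one row per participant).
#' @param ranges,mapping see \code{\link{categorize}}.
#' @return data.frame \code{participant_id} plus one logical column per
#'   category.
#' @export
categorize_panels <- function(labs, ranges = reference_ranges(),
                              mapping = category_mapping()) {
  n <- nrow(labs)
  abn <- function(analyte) {
    v <- labs[[analyte]]
    if (is.null(v)) return(rep(FALSE, n))
    out <- flag_analyte(analyte, v, labs$sex, ranges) %in% c("low", "high")
    out & !is.na(v)
  }
  roll <- function(analytes)
    Reduce(`|`, lapply(analytes, abn), rep(FALSE, n))
  eryth <- labs$erythroblasts_per_200 %||% rep(0, n)
  eryth[is.na(eryth)] <- 0
  out <- data.frame(
    participant_id = labs$participant_id,
    blood_sugar = roll(mapping$blood_sugar),
    renal = roll(mapping$renal),
    lipid = as.logical(labs$lipid_abnormal) %in% TRUE,
    hematological = roll(mapping$hematological) |
      flag_abnormal_cells(labs$blast_cells %in% TRUE,
                          labs$atypical_cells %in% TRUE, eryth),
    liver = roll(mapping$liver),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a labs CSV
#'
#' Expects the header \code{participant_id,sex,crp,hemoglobin,platelets,}
#' \code{leukocytes,blood_sugar,ast,alt,creatinine,bun,uric_acid,sodium,}
#' \code{blast_cells,atypical_cells,erythroblasts_per_200,lipid_abnormal}.
#'
#' @param path file path.
#' @return data.frame of laboratory panels.
#' @export
read_labs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  required <- c("participant_id", "sex", "blood_sugar", "creatinine", "bun",
                "ast", "alt", "hemoglobin", "platelets", "leukocytes",
                "blast_cells", "atypical_cells", "erythroblasts_per_200",
                "lipid_abnormal")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("labs file lacks required column(s): ",
         paste(missing, collapse = ", "))
  num <- setdiff(required, c("participant_id", "sex", "blast_cells",
                             "atypical_cells", "lipid_abnormal"))
  if (any(vapply(df[num], function(x) any(x < 0, na.rm = TRUE), logical(1))))
    stop("labs file contains negative analyte values")
  df
}
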