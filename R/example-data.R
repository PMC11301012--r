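#' Example: abnormality co-occurrence tables among notified participants
#'
#' The ten pairwise 2x2 tables of laboratory abnormality categories observed
#' among the 254 recipients of home blood pressure urgent notifications in a
#' large Japanese community screening cohort. Category order: blood sugar,
#' renal, lipid, hematological, liver. These counts are the worked input for
#' \code{\link{association_report}}; the marginals are
#' blood sugar 118, renal 101, lipid 90, hematological 42, liver 28 of 254.
#'
#' @return named list of ten \code{\link{contingency_2x2}} objects, keyed
#'   \code{"row:col"}.
#' @export
example_category_tables <- function() {
  t2 <- function(a, b, c, d, row, col)
    contingency_2x2(a, b, c, d, row_label = row, col_label = col)
  list(
    "blood_sugar:renal"   = t2(51, 67, 50,  86, "blood_sugar", "renal"),
    "blood_sugar:lipid"   = t2(85, 33,  5, 131, "blood_sugar", "lipid"),
    "blood_sugar:hematological" = t2(17, 101, 25, 111, "blood_sugar", "hematological"),
    "blood_sugar:liver"   = t2(18, 100, 10, 126, "blood_sugar", "liver"),
    "renal:lipid"         = t2(40, 61, 50, 103, "renal", "lipid"),
    "renal:hematological" = t2(19, 82, 23, 130, "renal", "hematological"),
    "renal:liver"         = t2(12, 89, 16, 137, "renal", "liver"),
    "lipid:hematological" = t2(11, 79, 31, 133, "lipid", "hematological"),
    "lipid:liver"         = t2(13, 77, 15, 149, "lipid", "liver"),
    "hematological:liver" = t2(3, 39, 25, 187, "hematological", "liver"))
}

#' Example: pre/post notification treatment-status survey counts
#'
#' Questionnaire counts on hypertension treatment status among the 254
#' notified participants of the same screening cohort: the pre-survey
#' (228 respondents), the post-notification survey (163 respondents), and
#' the subgroup of 151 participants who answered both waves. Categories in
#' the order of \code{\link{response_categories}} (without
#' \code{no_answer} for the subgroup rows, where non-response does not
#' occur by construction).
#'
#' @return list with named integer vectors \code{pre}, \code{post} (six
#'   categories including \code{no_answer}), \code{subgroup_pre},
#'   \code{subgroup_post} (five answer categories) and \code{n_notified}.
#' @export
example_treatment_survey <- function() {
  ans <- answer_categories()
  list(
    pre = setNames(c(95L, 15L, 39L, 24L, 55L, 26L), response_categories()),
    post = setNames(c(116L, 3L, 21L, 8L, 15L, 91L), response_categories()),
    subgroup_pre = setNames(c(68L, 7L, 25L, 14L, 37L), ans),
    subgroup_post = setNames(c(107L, 3L, 20L, 8L, 13L), ans),
    n_notified = 254L)
}

#' Expand survey counts into a response table
#'
#' Builds a long-format response data.frame (one row per participant and
#' wave) whose per-wave tabulations reproduce the supplied counts. Used to
#' feed printed summary counts through \code{\link{tabulate_responses}}.
#'
#' @param counts named integer vector over (a subset of)
#'   \code{\link{response_categories}}.
#' @param wave \code{"pre"} or \code{"post"}.
#' @param id_prefix prefix for generated participant ids.
#' @return data.frame \code{participant_id}, \code{wave}, \code{category}.
#' @export
expand_survey_counts <- function(counts, wave, id_prefix = "S") {
  category <- rep(names(counts), counts)
  data.frame(
    participant_id = sprintf("%s%04d", id_prefix, seq_along(category)),
    wave = wave, category = category, stringsAsFactors = FALSE)
}
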