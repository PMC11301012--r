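#' Questionnaire response categories
#'
#' The five hypertension-care answer categories plus \code{no_answer}
#' (questionnaire not returned or the item left blank). Percentages in
#' summaries are computed over respondents only, i.e. excluding
#' \code{no_answer}.
#'
#' @return character vector of the six category codes.
#' @export
response_categories <- function() {
  c("regular_treatment", "discontinued_followup", "lifestyle_precaution",
    "followup_no_medication", "never_pointed_out", "no_answer")
}

answer_categories <- function() setdiff(response_categories(), "no_answer")

check_responses <- function(responses) {
  required <- c("participant_id", "wave", "category")
  missing <- setdiff(required, names(responses))
  if (length(missing) > 0)
    stop("responses lack required column(s): ",
         paste(missing, collapse = ", "))
  bad <- setdiff(unique(responses$category), response_categories())
  if (length(bad) > 0)
    stop("unknown response category: ", paste(bad, collapse = ", "))
  if (!all(responses$wave %in% c("pre", "post")))
    stop("wave must be 'pre' or 'post'")
  dup <- duplicated(responses[c("participant_id", "wave")])
  if (any(dup))
    stop("duplicate response for participant(s) ",
         paste(unique(responses$participant_id[dup]), collapse = ", "),
         " in one wave")
  invisible(responses)
}

#' Tabulate one questionnaire wave
#'
#' Counts responses per category and computes percentages over respondents
#' (participants whose answer is not \code{no_answer}), rounded half-up to
#' one decimal as in clinical report tables.
#'
#' @param responses data.frame with columns \code{participant_id},
#'   \code{wave} (\code{"pre"}/\code{"post"}) and \code{category}.
#' @param wave which wave to tabulate.
#' @return an object of class \code{"behavior_summary"}: a list with
#'   \code{wave}, \code{counts} (named, the five answer categories plus
#'   \code{no_answer}), \code{n_respondents} and \code{percent} (named, the
#'   five answer categories).
#' @export
tabulate_responses <- function(responses, wave = c("pre", "post")) {
  wave <- match.arg(wave)
  check_responses(responses)
  responses <- responses[responses$wave == wave, , drop = FALSE]
  counts <- vapply(response_categories(),
                   function(k) sum(responses$category == k), integer(1))
  n_resp <- sum(counts[answer_categories()])
  percent <- if (n_resp > 0)
    round_half_up(100 * counts[answer_categories()] / n_resp, 1)
  else setNames(rep(NA_real_, 5), answer_categories())
  structure(list(wave = wave, counts = counts, n_respondents = n_resp,
                 percent = percent),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf("%s survey (n = %d respondents)\n",
              if (x$wave == "pre") "Pre" else "Post-notification",
              x$n_respondents))
  for (k in answer_categories())
    cat(sprintf("  %-24s %4d (%.1f%%)\n", k, x$counts[[k]], x$percent[[k]]))
  cat(sprintf("  %-24s %4d\n", "no_answer", x$counts[["no_answer"]]))
  invisible(x)
}

#' Participants who answered both waves
#'
#' Restricts to participants with a substantive (non-\code{no_answer})
#' response in both the pre-survey and the post-notification questionnaire.
#'
#' @param responses data.frame of responses in both waves.
#' @return data.frame \code{participant_id}, \code{pre}, \code{post},
#'   ordered by participant id.
#' @export
paired_subgroup <- function(responses) {
  check_responses(responses)
  answered <- responses[responses$category != "no_answer", , drop = FALSE]
  pre <- answered[answered$wave == "pre", c("participant_id", "category")]
  post <- answered[answered$wave == "post", c("participant_id", "category")]
  both <- merge(pre, post, by = "participant_id",
                suffixes = c("_pre", "_post"))
  out <- data.frame(participant_id = both$participant_id,
                    pre = both$category_pre, post = both$category_post,
                    stringsAsFactors = FALSE)
  out <- out[order(out$participant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' McNemar's test on paired care-seeking status
#'
#' Dichotomises the paired responses as \code{positive} (by default
#' \code{"regular_treatment"}) versus the total of the other behaviours, and
#' tests marginal change with the continuity-corrected McNemar statistic
#' \eqn{(|b - c| - 1)^2 / (b + c)} on the discordant counts \code{b}
#' (positive pre only) and \code{c} (positive post only), referred to the
#' chi-squared distribution with 1 df. When \code{b + c < 25} an exact
#' two-sided binomial p-value is also reported. With no discordant pairs the
#' p-value is 1 and a note is attached.
#'
#' @param pre,post character vectors of paired categories (same length,
#'   same participant order), e.g. the columns of
#'   \code{\link{paired_subgroup}}.
#' @param positive the category treated as the positive state.
#' @param correct apply the continuity correction (default TRUE).
#' @return an object of class \code{"mcnemar_result"}: list with \code{b},
#'   \code{c}, \code{statistic}, \code{p_value}, \code{p_exact} (NA unless
#'   computed) and \code{note}.
#' @export
mcnemar_paired <- function(pre, post, positive = "regular_treatment",
                           correct = TRUE) {
  stopifnot(length(pre) == length(post))
  x <- pre == positive
  y <- post == positive
  b <- sum(x & !y)
  c <- sum(!x & y)
  if (b + c == 0) {
    return(structure(list(b = b, c = c, statistic = NA_real_, p_value = 1,
                          p_exact = 1, note = "no discordant pairs"),
                     class = "mcnemar_result"))
  }
  num <- abs(b - c)
  if (correct) num <- max(num - 1, 0)
  stat <- num^2 / (b + c)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p_exact <- if (b + c < 25) {
    min(1, 2 * stats::pbinom(min(b, c), b + c, 0.5))
  } else NA_real_
  structure(list(b = b, c = c, statistic = stat, p_value = p,
                 p_exact = p_exact, note = NA_character_),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat("McNemar's chi-squared test (continuity corrected)\n")
  cat(sprintf("  discordant pairs: b = %d, c = %d\n", x$b, x$c))
  if (is.finite(x$statistic))
    cat(sprintf("  statistic = %.4f, p = %s\n", x$statistic,
                format_pvalue(x$p_value)))
  else cat(sprintf("  p = %s\n", format_pvalue(x$p_value)))
  if (!is.na(x$p_exact))
    cat(sprintf("  exact binomial p = %s\n", format_pvalue(x$p_exact)))
  if (!is.na(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Full behaviour-change report
#'
#' Tabulates both waves over all responses, forms the both-wave subgroup,
#' tabulates it, and runs McNemar's test on regular treatment versus the
#' other behaviours within the subgroup.
#'
#' @param responses data.frame of responses in both waves.
#' @param positive passed to \code{\link{mcnemar_paired}}.
#' @return an object of class \code{"behavior_report"}: list with
#'   \code{pre}, \code{post} (\code{behavior_summary}), \code{subgroup}
#'   (paired data.frame), \code{subgroup_pre}, \code{subgroup_post}
#'   (summaries over the subgroup) and \code{mcnemar}.
#' @export
behavior_report <- function(responses, positive = "regular_treatment") {
  pre <- tabulate_responses(responses, "pre")
  post <- tabulate_responses(responses, "post")
  pairs <- paired_subgroup(responses)
  sub_long <- rbind(
    data.frame(participant_id = pairs$participant_id, wave = "pre",
               category = pairs$pre, stringsAsFactors = FALSE),
    data.frame(participant_id = pairs$participant_id, wave = "post",
               category = pairs$post, stringsAsFactors = FALSE))
  structure(list(
    pre = pre, post = post, subgroup = pairs,
    subgroup_pre = tabulate_responses(sub_long, "pre"),
    subgroup_post = tabulate_responses(sub_long, "post"),
    mcnemar = mcnemar_paired(pairs$pre, pairs$post, positive)),
    class = "behavior_report")
}

#' @export
print.behavior_report <- function(x, ...) {
  cat("Effect of urgent notification on care-seeking behaviour\n\n")
  print(x$pre); cat("\n"); print(x$post)
  cat(sprintf("\nSubgroup answering both waves (n = %d)\n\n",
              nrow(x$subgroup)))
  print(x$subgroup_pre); cat("\n"); print(x$subgroup_post); cat("\n")
  print(x$mcnemar)
  invisible(x)
}
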