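test_that("wave tabulation reproduces counts and respondent percentages", {
  survey <- example_treatment_survey()
  responses <- rbind(expand_survey_counts(survey$pre, "pre"),
                     expand_survey_counts(survey$post, "post"))
  pre <- tabulate_responses(responses, "pre")
  expect_equal(pre$n_respondents, 228)
  expect_equal(unname(pre$percent["regular_treatment"]), 41.7)
  expect_equal(unname(pre$counts["no_answer"]), 26)

  post <- tabulate_responses(responses, "post")
  expect_equal(post$n_respondents, 163)
  expect_equal(unname(post$percent["regular_treatment"]), 71.2)

  # respondent percentages sum to 100 up to rounding
  expect_lt(abs(sum(pre$percent) - 100), 0.3)
  expect_lt(abs(sum(post$percent) - 100), 0.3)
})

test_that("degenerate and random tabulations match a naive tally", {
  one <- data.frame(participant_id = c("a", "b"), wave = "pre",
                    category = "never_pointed_out", stringsAsFactors = FALSE)
  s <- tabulate_responses(one, "pre")
  expect_equal(unname(s$percent["never_pointed_out"]), 100.0)

  set.seed(71)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    cats <- sample(response_categories(), n, replace = TRUE)
    df <- data.frame(participant_id = sprintf("q%03d", 1:n), wave = "post",
                     category = cats, stringsAsFactors = FALSE)
    s <- tabulate_responses(df, "post")
    n_resp <- sum(cats != "no_answer")
    expect_equal(s$n_respondents, n_resp)
    for (k in setdiff(response_categories(), "no_answer"))
      expect_equal(unname(s$percent[k]),
                   round_half_up(100 * sum(cats == k) / n_resp, 1))
  }
})

test_that("duplicate responses within a wave are rejected", {
  dup <- data.frame(participant_id = c("a", "a"), wave = "pre",
                    category = "regular_treatment", stringsAsFactors = FALSE)
  expect_error(tabulate_responses(dup, "pre"), "duplicate")
})

test_that("the paired subgroup keeps only both-wave respondents", {
  resp <- data.frame(
    participant_id = c("a", "a", "b", "c", "c", "d", "d"),
    wave = c("pre", "post", "pre", "pre", "post", "pre", "post"),
    category = c("never_pointed_out", "regular_treatment",
                 "regular_treatment", "lifestyle_precaution", "no_answer",
                 "regular_treatment", "regular_treatment"),
    stringsAsFactors = FALSE)
  pairs <- paired_subgroup(resp)
  expect_equal(pairs$participant_id, c("a", "d"))  # b: pre only; c: post no_answer
  expect_equal(pairs$pre, c("never_pointed_out", "regular_treatment"))
  expect_equal(pairs$post, c("regular_treatment", "regular_treatment"))
})

test_that("a constructed overlap of size k yields exactly k pairs", {
  set.seed(72)
  ids <- sprintf("p%03d", 1:60)
  both <- sample(ids, 23)
  pre_only <- sample(setdiff(ids, both), 15)
  post_only <- setdiff(ids, c(both, pre_only))
  resp <- rbind(
    data.frame(participant_id = c(both, pre_only), wave = "pre",
               category = "lifestyle_precaution", stringsAsFactors = FALSE),
    data.frame(participant_id = c(both, post_only), wave = "post",
               category = "regular_treatment", stringsAsFactors = FALSE))
  expect_equal(nrow(paired_subgroup(resp)), 23)
})

test_that("McNemar statistic follows the corrected closed form", {
  # b = 5, c = 15: (|5-15| - 1)^2 / 20
  pre <- c(rep("regular_treatment", 5), rep("never_pointed_out", 15))
  post <- c(rep("never_pointed_out", 5), rep("regular_treatment", 15))
  res <- mcnemar_paired(pre, post)
  expect_equal(res$statistic, 4.05)
  expect_equal(res$b, 5)
  expect_equal(res$c, 15)
  # cross-check against base R on the full paired table
  tab <- table(factor(pre == "regular_treatment", c(FALSE, TRUE)),
               factor(post == "regular_treatment", c(FALSE, TRUE)))
  ref <- mcnemar.test(tab, correct = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  # b + c < 25: the exact binomial companion p is reported
  expect_equal(res$p_exact, min(1, 2 * pbinom(5, 20, 0.5)))
})

test_that("McNemar is symmetric in the discordant counts and handles
           degenerate pairings", {
  pre <- c(rep("regular_treatment", 15), rep("never_pointed_out", 5))
  post <- c(rep("never_pointed_out", 15), rep("regular_treatment", 5))
  flip <- mcnemar_paired(pre, post)
  expect_equal(flip$statistic, 4.05)
  expect_equal(flip$p_value, mcnemar_paired(post, pre)$p_value)

  none <- mcnemar_paired(rep("regular_treatment", 4),
                         rep("regular_treatment", 4))
  expect_equal(none$p_value, 1)
  expect_equal(none$note, "no discordant pairs")

  oneway <- mcnemar_paired(rep("never_pointed_out", 39),
                           rep("regular_treatment", 39))
  expect_lt(oneway$p_value, 0.001)
  expect_equal(oneway$statistic, (39 - 1)^2 / 39)
})

test_that("exact binomial and corrected chi-squared p-values converge for
           large discordant samples", {
  # The corrected statistic is the continuity-corrected normal
  # approximation of the doubled exact binomial tail, so the two agree
  # absolutely once b + c is large, except where the doubled tail
  # saturates at 1 (b close to c) and in the deep tail where relative
  # error is the meaningful scale.
  set.seed(73)
  for (rep in 1:40) {
    n <- sample(100:400, 1)
    b <- rbinom(1, n, runif(1, 0.25, 0.75))
    c <- n - b
    stat <- (max(abs(b - c) - 1, 0))^2 / n
    p_chisq <- pchisq(stat, 1, lower.tail = FALSE)
    p_exact <- min(1, 2 * pbinom(min(b, c), n, 0.5))
    if (p_exact <= 0.9)
      expect_lt(abs(p_chisq - p_exact), 0.02)
    if (p_exact >= 0.05 && p_exact <= 0.9)
      expect_lt(abs(p_chisq - p_exact) / p_exact, 0.05)
  }
})

test_that("behavior_report ties the pieces together", {
  survey <- example_treatment_survey()
  # construct responses with a known 151-participant overlap structure
  set.seed(74)
  resp <- rbind(
    expand_survey_counts(survey$subgroup_pre, "pre", id_prefix = "B"),
    expand_survey_counts(survey$subgroup_post, "post", id_prefix = "B"))
  rep_out <- behavior_report(resp)
  expect_equal(nrow(rep_out$subgroup), 151)
  expect_equal(unname(rep_out$subgroup_pre$percent["regular_treatment"]), 45.0)
  expect_equal(unname(rep_out$subgroup_post$percent["regular_treatment"]), 70.9)
  expect_s3_class(rep_out$mcnemar, "mcnemar_result")
})
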