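#' A 2x2 contingency table of participant counts
#'
#' Counts are laid out as \code{a} = (row+, col+), \code{b} = (row+, col-),
#' \code{c} = (row-, col+), \code{d} = (row-, col-).
#'
#' @param a,b,c,d nonnegative integer counts.
#' @param row_label,col_label category names for reporting.
#' @return an object of class \code{"contingency_2x2"}.
#' @export
contingency_2x2 <- function(a, b, c, d, row_label = "row", col_label = "col") {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (sum(counts) < 1) stop("table must contain at least one observation")
  structure(list(a = a, b = b, c = c, d = d,
                 row_label = row_label, col_label = col_label),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(paste(x$row_label, c("+", "-")),
                              paste(x$col_label, c("+", "-"))))
  print(m)
  invisible(x)
}

as_matrix_2x2 <- function(tab) {
  matrix(c(tab$a, tab$b, tab$c, tab$d), 2, byrow = TRUE)
}

new_assoc_test <- function(method, statistic, p_value, alpha, note = NA_character_) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 alpha = alpha, significant = is.finite(p_value) && p_value < alpha,
                 note = note),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("%s: %sp = %s%s (alpha = %g, %ssignificant)\n",
              switch(x$method,
                     pearson_yates = "Pearson chi-squared (Yates-corrected)",
                     fisher = "Fisher exact test", x$method),
              if (is.finite(x$statistic))
                sprintf("X-squared = %.4f, ", x$statistic) else "",
              format_pvalue(x$p_value),
              if (!is.na(x$note)) paste0(" [", x$note, "]") else "",
              x$alpha, if (x$significant) "" else "not "))
  invisible(x)
}

format_pvalue <- function(p) {
  ifelse(p < 1e-4, "<0.0001", formatC(signif(p, 4), format = "fg"))
}

#' Yates-corrected chi-squared test on a 2x2 table
#'
#' Pearson's chi-squared test with the continuity correction: the statistic
#' is \eqn{n (\max(|ad - bc| - n/2, 0))^2 / (r_1 r_2 c_1 c_2)} with the
#' marginal totals \eqn{r_1, r_2, c_1, c_2}; the (two-sided) p-value is the
#' upper tail of the chi-squared distribution with one degree of freedom.
#' The correction is clamped at zero, so a perfectly balanced table gives a
#' statistic of 0 and p = 1.
#'
#' @param table a \code{\link{contingency_2x2}}.
#' @param alpha significance level used to set the \code{significant} field.
#' @param correct apply the continuity correction (default TRUE).
#' @return an \code{"assoc_test"} with \code{method = "pearson_yates"},
#'   \code{statistic}, \code{p_value}, \code{significant}.
#' @export
chisq_yates <- function(table, alpha = 0.05, correct = TRUE) {
  stopifnot(inherits(table, "contingency_2x2"))
  a <- as.numeric(table$a); b <- as.numeric(table$b)
  c <- as.numeric(table$c); d <- as.numeric(table$d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0)
    stop("zero marginal total: the chi-squared test is undefined; ",
         "use fisher_exact()")
  num <- abs(a * d - b * c)
  if (correct) num <- max(num - n / 2, 0)
  stat <- n * num^2 / (r1 * r2 * c1 * c2)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  new_assoc_test(if (correct) "pearson_yates" else "pearson", stat, p, alpha)
}

#' Fisher's exact test on a 2x2 table (two-sided)
#'
#' Conditions on both margins: under the null the count \code{a} is
#' hypergeometric. The two-sided p-value sums the probabilities of all
#' tables with the observed margins whose point probability does not exceed
#' that of the observed table, with a relative tolerance of 1e-7 for ties
#' (the usual convention in statistical software).
#'
#' @param table a \code{\link{contingency_2x2}}.
#' @param alpha significance level used to set the \code{significant} field.
#' @return an \code{"assoc_test"} with \code{method = "fisher"} and no
#'   statistic.
#' @export
fisher_exact <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "contingency_2x2"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, c1 - (c + d)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- probs[match(a, support)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  new_assoc_test("fisher", NA_real_, min(p, 1), alpha)
}

#' Choose between the chi-squared and Fisher tests for a 2x2 table
#'
#' Uses Fisher's exact test when the smallest observed cell count is at most
#' \code{fisher_threshold} (default 5), and the Yates-corrected chi-squared
#' test otherwise. This small-cell rule mirrors common practice for sparse
#' tables; either method can be forced via the \code{method} argument of
#' \code{\link{association_report}}.
#'
#' @param table a \code{\link{contingency_2x2}}.
#' @param fisher_threshold smallest-cell cutoff at or below which Fisher is
#'   selected.
#' @return \code{"fisher"} or \code{"pearson_yates"}.
#' @export
select_test <- function(table, fisher_threshold = 5) {
  stopifnot(inherits(table, "contingency_2x2"))
  if (min(table$a, table$b, table$c, table$d) <= fisher_threshold)
    "fisher" else "pearson_yates"
}

#' Association tests over a set of 2x2 tables with Bonferroni control
#'
#' Applies the test-selection rule (or a forced method) to each table and
#' marks significance at the Bonferroni-adjusted level
#' \code{alpha_family / length(tables)}.
#'
#' @param tables list of \code{\link{contingency_2x2}} objects.
#' @param alpha_family family-wise significance level (default 0.05).
#' @param method \code{"auto"} (selection rule), \code{"pearson_yates"} or
#'   \code{"fisher"}.
#' @param fisher_threshold passed to \code{\link{select_test}}.
#' @return an object of class \code{"assoc_report"}: a data.frame with one
#'   row per table (\code{row_label}, \code{col_label}, the four counts,
#'   \code{method}, \code{statistic}, \code{p_value}, \code{alpha},
#'   \code{significant}, \code{note}).
#' @export
association_report <- function(tables, alpha_family = 0.05, method = "auto",
                               fisher_threshold = 5) {
  alpha <- alpha_family / length(tables)
  rows <- lapply(tables, function(tab) {
    stopifnot(inherits(tab, "contingency_2x2"))
    degenerate <- with(tab, min(a + b, c + d) == 0 || min(a + c, b + d) == 0)
    if (degenerate) {
      res <- new_assoc_test("degenerate", NA_real_, 1, alpha,
                            note = "degenerate table: a margin is zero")
    } else {
      m <- if (method == "auto") select_test(tab, fisher_threshold) else method
      res <- switch(m,
                    pearson_yates = chisq_yates(tab, alpha),
                    fisher = fisher_exact(tab, alpha),
                    stop("unknown method: ", m))
    }
    data.frame(row_label = tab$row_label, col_label = tab$col_label,
               a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               method = res$method, statistic = res$statistic,
               p_value = res$p_value, alpha = alpha,
               significant = res$significant, note = res$note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("assoc_report", "data.frame")
  out
}

#' Pairwise association of abnormality categories
#'
#' Builds the C(5,2) = 10 contingency tables over the unordered pairs of
#' abnormality categories (in the order blood sugar, renal, lipid,
#' hematological, liver), applies the test-selection rule and Bonferroni
#' control at \code{alpha_family / 10}. A category with no variation makes
#' each of its pairs degenerate: those rows carry p = 1 and a note.
#'
#' @param flags data.frame of category flags (one row per participant;
#'   logical columns named as in \code{\link{category_names}}), typically
#'   restricted to notified participants.
#' @param alpha_family family-wise significance level (default 0.05).
#' @param method,fisher_threshold see \code{\link{association_report}}.
#' @return an \code{"assoc_report"} with 10 rows.
#' @export
pairwise_association <- function(flags, alpha_family = 0.05, method = "auto",
                                 fisher_threshold = 5) {
  cats <- category_names()
  missing <- setdiff(cats, names(flags))
  if (length(missing) > 0)
    stop("flags lack category column(s): ", paste(missing, collapse = ", "))
  if (nrow(flags) < 2) stop("need at least 2 participants")
  tables <- list()
  for (i in seq_along(cats)) for (j in seq_along(cats)) {
    if (j <= i) next
    x <- as.logical(flags[[cats[i]]]); y <- as.logical(flags[[cats[j]]])
    tables[[length(tables) + 1]] <- contingency_2x2(
      sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y),
      row_label = cats[i], col_label = cats[j])
  }
  association_report(tables, alpha_family, method, fisher_threshold)
}

#' @export
print.assoc_report <- function(x, ...) {
  cat(sprintf(
    "Pairwise association of abnormality categories (%d tables)\n", nrow(x)))
  cat(sprintf("Bonferroni-adjusted per-test alpha = %g\n\n", x$alpha[1]))
  marker <- ifelse(x$method == "fisher", "^2",
                   ifelse(x$method == "pearson_yates", "^1", "  "))
  cat(sprintf("  %-14s x %-14s %4s %4s %4s %4s  p = %-8s%s%s\n",
              x$row_label, x$col_label, x$a, x$b, x$c, x$d,
              format_pvalue(x$p_value), marker,
              ifelse(x$significant, " *", "")), sep = "")
  cat("\n  ^1 Pearson chi-squared (Yates-corrected)  ^2 Fisher exact",
      " * significant\n")
  invisible(x)
}
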