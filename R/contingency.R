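#' A 2x2 contingency table
#'
#' Counts for an exposure/event cross-classification: `a` exposed with
#' event, `b` exposed without, `c` unexposed with event, `d` unexposed
#' without. In the base-deficit analysis "exposed" is the BD >= 4
#' stratum and the event is e.g. surgery or transfusion within 24 h.
#'
#' @param a,b,c,d Nonnegative integer counts.
#' @return Object of class `contingency_2x2`.
#' @export
#' @examples
#' contingency_2x2(51, 33, 29, 41)  # surgical intervention by stratum
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("contingency_2x2: counts must be nonnegative integers")
  structure(lapply(as.list(counts), as.integer), class = "contingency_2x2")
}

.as_matrix_2x2 <- function(tab) {
  matrix(c(tab$a, tab$c, tab$b, tab$d), nrow = 2,
         dimnames = list(c("exposed", "unexposed"), c("event", "no_event")))
}

#' Relative risk with Katz log confidence interval
#'
#' Risk ratio `(a/(a+b)) / (c/(c+d))` with the Katz log-method interval
#' `exp(log(rr) +/- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. A zero
#' event count in either row makes the log variance infinite; set
#' `correction = TRUE` to add 0.5 to every cell (documented
#' continuity-corrected variant, off by default).
#'
#' @param table A [contingency_2x2()].
#' @param alpha Two-sided level for the CI (default 0.05 -> 95% CI).
#' @param correction Add 0.5 to all cells before computing.
#' @return List of class `relative_risk_result`: `rr`, `ci_low`,
#'   `ci_high`, `alpha`.
#' @export
#' @examples
#' relative_risk(contingency_2x2(51, 33, 29, 41))  # rr 1.47, CI 1.056-2.033
relative_risk <- function(table, alpha = 0.05, correction = FALSE) {
  stopifnot(inherits(table, "contingency_2x2"))
  k <- if (correction) 0.5 else 0
  a <- table$a + k; b <- table$b + k; c <- table$c + k; d <- table$d + k
  if (a + b <= 0 || c + d <= 0)
    stop("relative_risk: both exposure rows must have observations")
  if (a == 0 || c == 0)
    stop("relative_risk: zero event count; use correction = TRUE for the ",
         "continuity-corrected variant")
  rr <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(rr = rr, ci_low = rr * exp(-z * se),
                 ci_high = rr * exp(z * se), alpha = alpha),
            class = "relative_risk_result")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson chi-square by default (Yates continuity
#' correction behind `correct = TRUE`), with the p-value from the
#' chi-square distribution on 1 df.
#'
#' @param table A [contingency_2x2()].
#' @param correct Apply the Yates correction.
#' @return List with `statistic` and `p`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  stopifnot(inherits(table, "contingency_2x2"))
  m <- .as_matrix_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi_square_2x2: degenerate margins (zero row or column total)")
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided exact p-value obtained by summing hypergeometric
#' probabilities no larger than the observed table's.
#'
#' @param table A [contingency_2x2()].
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  unname(stats::fisher.test(.as_matrix_2x2(table))$p.value)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples with midrank handling
#' of ties. The p-value is exact (enumeration) when the combined sample
#' size is at most 12 and there are no ties, and otherwise uses the
#' normal approximation with the tie-corrected variance; two-sided.
#'
#' @param x,y Numeric samples, each nonempty.
#' @return List with `U` (the U statistic of `x`) and `p`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y))
    stop("mann_whitney_u: both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 12
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact))
  list(U = unname(res$statistic), p = unname(res$p.value))
}
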