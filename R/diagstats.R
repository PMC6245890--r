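#' Cross-tabulate binary calls against truth
#'
#' @param calls,truth equal-length 0/1 (or logical) vectors.
#' @return Object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(calls, truth) {
  if (length(calls) != length(truth))
    stop("'calls' and 'truth' must have equal length")
  calls <- as.integer(as.logical(calls))
  truth <- as.integer(as.logical(truth))
  structure(list(tp = sum(calls == 1 & truth == 1),
                 fp = sum(calls == 1 & truth == 0),
                 tn = sum(calls == 0 & truth == 0),
                 fn = sum(calls == 0 & truth == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("          truth+  truth-\n  call+   %6d  %6d\n  call-   %6d  %6d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Sensitivity, specificity and agreement with exact confidence intervals
#'
#' Percentages are computed from the counts as exact rationals and reported
#' rounded to one decimal (half away from zero); confidence intervals are
#' exact Clopper-Pearson. A statistic whose denominator is zero is reported
#' as `NA` (undefined).
#'
#' @param counts a `confusion_counts` object (or list with `tp, fp, tn, fn`).
#' @param conf_level confidence level for the intervals.
#' @return Object of class `accuracy_stats`: data.frame with columns
#'   `statistic`, `numerator`, `denominator`, `pct` (rounded to 1 decimal),
#'   `lo_pct`, `hi_pct`.
#' @export
accuracy_stats <- function(counts, conf_level = 0.95) {
  one <- function(name, num, den) {
    if (den == 0)
      return(data.frame(statistic = name, numerator = num, denominator = 0,
                        pct = NA_real_, lo_pct = NA_real_,
                        hi_pct = NA_real_))
    ci <- stats::binom.test(num, den, conf.level = conf_level)$conf.int
    data.frame(statistic = name, numerator = num, denominator = den,
               pct = round_half_up(100 * num / den),
               lo_pct = round_half_up(100 * ci[1]),
               hi_pct = round_half_up(100 * ci[2]))
  }
  out <- rbind(
    one("sensitivity", counts$tp, counts$tp + counts$fn),
    one("specificity", counts$tn, counts$tn + counts$fp),
    one("agreement", counts$tp + counts$tn,
        counts$tp + counts$fp + counts$tn + counts$fn))
  structure(out, class = c("accuracy_stats", "data.frame"))
}

#' Exact McNemar test for paired dichotomous data
#'
#' Exact two-sided binomial test of `b` successes in `b + c` trials at
#' probability 1/2 (the discordant-pair counts of a paired 2x2 table),
#' with the p-value capped at 1; `b + c = 0` gives p = 1. The asymptotic
#' chi-square variant is available via `method`.
#'
#' @param b,c discordant-pair counts (non-negative integers).
#' @param method `"exact"` (default) or `"asymptotic"`.
#' @return The two-sided p-value.
#' @export
mcnemar_exact <- function(b, c, method = c("exact", "asymptotic")) {
  method <- match.arg(method)
  if (b < 0 || c < 0) stop("discordant counts must be non-negative")
  n <- b + c
  if (n == 0) return(1)
  if (method == "asymptotic")
    return(stats::pchisq((b - c)^2 / n, df = 1, lower.tail = FALSE))
  min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Classical (equal-variance) one-way ANOVA across groups, followed by
#' pairwise two-sample t tests whose p-values are multiplied by the number
#' of comparisons (capped at 1).
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length.
#' @return List with `f` (ANOVA F statistic), `p`, and `pairwise` (a
#'   data.frame with `group1`, `group2`, `p_raw`, `p_bonferroni`).
#' @export
group_compare <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2)) stop("every group needs at least 2 values")
  av <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  pairs <- utils::combn(levels(groups), 2)
  m <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(m), function(i) {
    a <- values[groups == pairs[1, i]]
    b <- values[groups == pairs[2, i]]
    p <- stats::t.test(a, b, var.equal = TRUE)$p.value
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i], p_raw = p,
               p_bonferroni = min(1, p * m))
  }))
  list(f = unname(av$statistic), p = unname(av$p.value), pairwise = pw)
}

#' Compare two proportions
#'
#' Pearson chi-square (without continuity correction) or two-sided Fisher
#' exact test of `a/n1` versus `b/n2`. Tables with a zero margin are only
#' testable with the Fisher method.
#'
#' @param a,n1 successes and size of the first group.
#' @param b,n2 successes and size of the second group.
#' @param method `"chi-square"` or `"fisher"`.
#' @return The two-sided p-value.
#' @export
proportions_test <- function(a, n1, b, n2,
                             method = c("chi-square", "fisher")) {
  method <- match.arg(method)
  if (any(c(a, b) < 0) || a > n1 || b > n2) stop("invalid counts")
  tab <- rbind(c(a, n1 - a), c(b, n2 - b))
  if (method == "chi-square") {
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      stop("zero-margin table: use method = \"fisher\"")
    return(suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$p.value))
  }
  stats::fisher.test(tab)$p.value
}
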