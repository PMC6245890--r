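#' Reference validation-cohort summary
#'
#' Summary counts of the 53-patient stress-perfusion validation cohort
#' shipped with the package, against invasive coronary angiography as the
#' reference standard: 16 patients CAD-positive, per-vessel lesion counts,
#' vessel-disease extent among positives, and the operating characteristics
#' of the quantitative analysis (which failed AIF quality control in 2
#' CAD-negative patients, leaving 51 analysable cases). Used by
#' [cohort_consistency_report()] as the fixture for the diagnostic-accuracy
#' arithmetic self-check.
#'
#' @return A list of named counts and reported percentages.
#' @export
cad_cohort <- function() {
  list(
    n = 53L, n_cad = 16L,
    quant_failures = 2L,              # both in CAD-negative patients
    vessel_counts = c(one = 8L, two = 5L, three = 3L),
    lesion_counts = c(LAD = 9L, LCX = 8L, RCA = 13L),
    reported = c(
      prevalence_pct = 30.2,
      quant_sensitivity_pct = 68.8,
      quant_specificity_pct = 94.3,
      quant_agreement_pct = 86.3,
      penalized_concordance_pct = 83.0,
      penalized_specificity_pct = 89.2,
      one_vessel_pct = 50.0,
      two_vessel_pct = 31.3,
      three_vessel_pct = 18.8,
      lad_prevalence_pct = 17.0,
      lcx_prevalence_pct = 15.1,
      rca_prevalence_pct = 24.5))
}

#' Recompute the validation cohort's printed accuracy arithmetic
#'
#' Re-derives every reported percentage of the reference cohort from the
#' underlying integer counts and checks it against the reported value:
#' CAD prevalence; the quantitative confusion matrix reconstructed from the
#' reported sensitivity/specificity on the 51 analysable cases
#' (nearest-integer rounding of rate x denominator, giving 11/16 true
#' positives and 33/35 true negatives); overall agreement; the
#' failure-penalized concordance and specificity obtained by counting the
#' 2 quality-control failures (both CAD-negative) as missed diagnoses; and
#' the vessel-extent and per-vessel lesion percentages.
#'
#' @param cohort a cohort summary, by default [cad_cohort()].
#' @return Object of class `cohort_report`: data.frame with columns
#'   `quantity`, `value` (recomputed, 1 decimal), `reported`, `pass`.
#' @export
cohort_consistency_report <- function(cohort = cad_cohort()) {
  n <- cohort$n
  pos <- cohort$n_cad
  analysable <- n - cohort$quant_failures
  neg <- analysable - pos
  rep_pct <- cohort$reported

  tp <- round(rep_pct[["quant_sensitivity_pct"]] / 100 * pos)
  fn <- pos - tp
  tn <- round(rep_pct[["quant_specificity_pct"]] / 100 * neg)
  fp <- neg - tn

  pct <- function(num, den) round_half_up(100 * num / den)
  values <- c(
    prevalence_pct = pct(pos, n),
    quant_sensitivity_pct = pct(tp, tp + fn),
    quant_specificity_pct = pct(tn, tn + fp),
    quant_agreement_pct = pct(tp + tn, analysable),
    # the 2 failed CAD-negative cases counted as misses
    penalized_concordance_pct = pct(tp + tn, n),
    penalized_specificity_pct = pct(tn, tn + fp + cohort$quant_failures),
    one_vessel_pct = pct(cohort$vessel_counts[["one"]], pos),
    two_vessel_pct = pct(cohort$vessel_counts[["two"]], pos),
    three_vessel_pct = pct(cohort$vessel_counts[["three"]], pos),
    lad_prevalence_pct = pct(cohort$lesion_counts[["LAD"]], n),
    lcx_prevalence_pct = pct(cohort$lesion_counts[["LCX"]], n),
    rca_prevalence_pct = pct(cohort$lesion_counts[["RCA"]], n))

  out <- data.frame(quantity = names(values), value = unname(values),
                    reported = unname(rep_pct[names(values)]),
                    pass = unname(values == rep_pct[names(values)]))
  attr(out, "confusion") <- confusion_from_counts(tp, fp, tn, fn)
  structure(out, class = c("cohort_report", "data.frame"))
}

confusion_from_counts <- function(tp, fp, tn, fn) {
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Validation-cohort consistency report\n")
  print.data.frame(x, row.names = FALSE)
  cat(if (all(x$pass)) "all quantities reproduced\n"
      else "MISMATCH in at least one quantity\n")
  invisible(x)
}
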