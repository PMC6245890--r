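#' Construct the dual-bolus arterial input function
#'
#' The AIF is the mean blood-pool signal per frame of the diluted pre-bolus
#' series, baseline-subtracted (mean of the first `n_baseline` frames) and
#' multiplied by the dilution factor (10 for the 0.0075 / 0.075 mmol/kg
#' dual-bolus protocol). Bolus arrival is the first frame exceeding
#' baseline + 3 SD(baseline); the quality score is peak enhancement over
#' baseline SD and feeds [qc_aif()].
#'
#' @param prebolus the pre-bolus [dynamic_series()].
#' @param blood_pool_mask logical array `[row, col, slice]` (or a matrix for
#'   a single-slice mask) selecting blood-pool pixels.
#' @param dilution main:pre-bolus dose ratio.
#' @param n_baseline number of pre-contrast frames for the baseline.
#' @return An object of class `perf_aif`: `times`, `values`
#'   (baseline-subtracted, dilution-corrected), `dilution`, `baseline`,
#'   `baseline_sd`, `arrival_index`, `arrival_time` (NA when no frame
#'   exceeds the threshold), `quality`.
#' @export
extract_aif <- function(prebolus, blood_pool_mask, dilution = 10,
                        n_baseline = 5) {
  stopifnot(inherits(prebolus, "dynamic_series"))
  d <- dim(prebolus$data)
  if (is.matrix(blood_pool_mask))
    blood_pool_mask <- array(blood_pool_mask, c(d[1], d[2], 1))
  if (!any(blood_pool_mask)) stop("blood-pool mask is empty")
  if (d[4] < n_baseline)
    stop("need at least ", n_baseline, " frames for the baseline")
  flat <- matrix(prebolus$data, nrow = prod(d[1:3]), ncol = d[4])
  px <- flat[as.vector(blood_pool_mask), , drop = FALSE]
  curve <- colMeans(px)
  baseline <- mean(curve[seq_len(n_baseline)])
  # SD of the mask-mean curve, estimated by pooling every masked pixel
  # sample over the baseline frames (stable even for few baseline frames)
  bsd <- stats::sd(px[, seq_len(n_baseline)]) / sqrt(nrow(px))
  arrival <- which(curve > baseline + 3 * bsd)[1]
  peak <- max(curve) - baseline
  quality <- if (bsd > 0) peak / bsd else if (peak > 0) Inf else 0
  structure(list(
    times = prebolus$times, values = (curve - baseline) * dilution,
    dilution = dilution, baseline = baseline, baseline_sd = bsd,
    arrival_index = arrival,
    arrival_time = if (is.na(arrival)) NA_real_ else
      prebolus$times[arrival],
    quality = quality), class = "perf_aif")
}

#' @export
print.perf_aif <- function(x, ...) {
  cat(sprintf(
    "<perf_aif> dilution x%g, peak %.4g, arrival %s s, quality %.3g\n",
    x$dilution, max(x$values), format(x$arrival_time), x$quality))
  invisible(x)
}

#' Quality control of the arterial input function
#'
#' A diluted pre-bolus whose peak enhancement is small relative to the
#' baseline noise cannot support quantification; such cases are recorded
#' as quantification failures rather than producing unreliable flow maps.
#'
#' @param aif a `perf_aif` from [extract_aif()].
#' @param min_quality minimum acceptable quality score (peak / baseline SD).
#' @return List with `pass` (logical), `quality`, `min_quality`.
#' @export
qc_aif <- function(aif, min_quality = 5) {
  stopifnot(inherits(aif, "perf_aif"))
  q <- aif$quality
  list(pass = is.finite(q) && q >= min_quality || is.infinite(q) && q > 0,
       quality = q, min_quality = min_quality)
}

#' Pixel-wise myocardial blood flow map
#'
#' Applies [fermi_deconvolve()] to the baseline-subtracted time-course of
#' every myocardial pixel, producing per-pixel MBF, residual RMS and
#' convergence maps. Single-pixel fit failures are recorded, never fatal.
#'
#' @param series a motion-corrected [dynamic_series()].
#' @param aif a `perf_aif` that passed [qc_aif()].
#' @param mask logical `[row, col, slice]` myocardial mask.
#' @param n_baseline frames used for the per-pixel signal baseline.
#' @param pre_smooth apply a 3x3 Gaussian spatial filter per frame first.
#' @param flow_scale reporting scale for `h(0)`; 60 converts 1/s to
#'   mL/g/min-equivalent units.
#' @param ... passed to [fermi_deconvolve()].
#' @return Object of class `mbf_map`: arrays `mbf`, `rss`, `converged`
#'   (NA outside the mask), plus `mask`, `flow_scale`, `n_failed`.
#' @export
pixelwise_mbf <- function(series, aif, mask, n_baseline = 5,
                          pre_smooth = FALSE, flow_scale = 60, ...) {
  stopifnot(inherits(series, "dynamic_series"), inherits(aif, "perf_aif"))
  d <- dim(series$data)
  if (is.matrix(mask)) mask <- array(mask, c(d[1], d[2], 1))
  mbf <- array(NA_real_, d[1:3])
  rss <- array(NA_real_, d[1:3])
  conv <- array(NA, d[1:3])
  if (!any(mask)) {
    warning("empty myocardial mask: returning an empty map")
    return(structure(list(mbf = mbf, rss = rss, converged = conv,
                          mask = mask, flow_scale = flow_scale,
                          n_failed = 0L), class = "mbf_map"))
  }
  dat <- series$data
  if (pre_smooth) {
    kern <- outer(stats::dnorm(-1:1, sd = 0.8), stats::dnorm(-1:1, sd = 0.8))
    kern <- kern / sum(kern)
    for (s in seq_len(d[3])) for (f in seq_len(d[4]))
      dat[, , s, f] <- EBImage::filter2(dat[, , s, f], kern)
  }
  n_failed <- 0L
  for (s in seq_len(d[3])) {
    idx <- which(mask[, , s], arr.ind = TRUE)
    for (i in seq_len(nrow(idx))) {
      tc <- dat[idx[i, 1], idx[i, 2], s, ]
      tc <- tc - mean(tc[seq_len(n_baseline)])
      fit <- tryCatch(
        suppressWarnings(fermi_deconvolve(aif, tc, flow_scale = flow_scale,
                                          ...)),
        error = function(e) NULL)
      if (is.null(fit)) {
        n_failed <- n_failed + 1L
        next
      }
      mbf[idx[i, 1], idx[i, 2], s] <- fit$mbf
      rss[idx[i, 1], idx[i, 2], s] <- fit$rss
      conv[idx[i, 1], idx[i, 2], s] <- fit$converged
    }
  }
  if (n_failed > 0)
    warning(n_failed, " pixel fit(s) failed and were left NA")
  structure(list(mbf = mbf, rss = rss, converged = conv, mask = mask,
                 flow_scale = flow_scale, n_failed = n_failed),
            class = "mbf_map")
}

#' @export
print.mbf_map <- function(x, ...) {
  v <- x$mbf[x$mask & !is.na(x$mbf)]
  cat(sprintf(
    "<mbf_map> %d fitted pixels; MBF median %.3g [%.3g, %.3g]; %d failed\n",
    length(v), stats::median(v), min(v), max(v), x$n_failed))
  invisible(x)
}

#' Per-segment MBF, MPR and ischemia calls
#'
#' Summarizes stress and rest MBF maps over the AHA 16-segment map:
#' per-segment MBF is the median (or mean) over converged pixels, MPR the
#' stress/rest ratio (`mpr_order = "segment"`, the default) or the
#' per-pixel MPR median (`"pixel"`), and a segment is called ischemic when
#' MPR < `threshold` (strictly; a segment at exactly the threshold is
#' negative). A territory is positive when at least `min_ischemic_segments`
#' of its segments are ischemic; the patient is positive when any territory
#' is. Segments with non-positive rest MBF are marked indeterminate and
#' excluded with a warning.
#'
#' @param stress_map,rest_map `mbf_map` objects on shared geometry.
#' @param segmap a `segment_map` from [build_segment_map()].
#' @param stat per-segment summary statistic.
#' @param mpr_order ratio of segment summaries, or summary of pixel ratios.
#' @param threshold MPR ischemia threshold.
#' @param min_ischemic_segments segments required to call a territory.
#' @return Object of class `segment_table`: a data.frame with columns
#'   `segment`, `territory`, `mbf_stress`, `mbf_rest`, `mpr`, `ischemic`,
#'   with attributes `territory_calls` (named logical) and `patient_call`.
#' @export
segment_summary <- function(stress_map, rest_map, segmap,
                            stat = c("median", "mean"),
                            mpr_order = c("segment", "pixel"),
                            threshold = 1.5, min_ischemic_segments = 1) {
  stat <- match.arg(stat)
  mpr_order <- match.arg(mpr_order)
  stopifnot(inherits(stress_map, "mbf_map"), inherits(rest_map, "mbf_map"),
            inherits(segmap, "segment_map"))
  if (!all(dim(stress_map$mbf) == dim(segmap$labels)) ||
      !all(dim(rest_map$mbf) == dim(segmap$labels)))
    stop("maps and segment map must share geometry")
  agg <- if (stat == "median") stats::median else mean
  terr <- segment_territories()
  mbf_s <- mbf_r <- mpr <- rep(NA_real_, 16)
  for (seg in 1:16) {
    in_seg <- segmap$labels == seg
    ok_s <- in_seg & !is.na(stress_map$converged) & stress_map$converged
    ok_r <- in_seg & !is.na(rest_map$converged) & rest_map$converged
    if (any(ok_s)) mbf_s[seg] <- agg(stress_map$mbf[ok_s])
    if (any(ok_r)) mbf_r[seg] <- agg(rest_map$mbf[ok_r])
    if (mpr_order == "segment") {
      if (!is.na(mbf_s[seg]) && !is.na(mbf_r[seg]) && mbf_r[seg] > 0)
        mpr[seg] <- mbf_s[seg] / mbf_r[seg]
    } else {
      ok <- ok_s & ok_r & rest_map$mbf > 0
      if (any(ok))
        mpr[seg] <- agg(stress_map$mbf[ok] / rest_map$mbf[ok])
    }
  }
  indet <- is.na(mpr)
  if (any(indet))
    warning("segment(s) ", paste(which(indet), collapse = ", "),
            " indeterminate (no converged pixels or non-positive rest MBF)",
            "; excluded from ischemia calling")
  ischemic <- ifelse(indet, NA, mpr < threshold)
  terr_calls <- vapply(c("LAD", "RCA", "LCX"), function(v)
    sum(ischemic[terr == v], na.rm = TRUE) >= min_ischemic_segments,
    logical(1))
  out <- data.frame(segment = 1:16, territory = terr, mbf_stress = mbf_s,
                    mbf_rest = mbf_r, mpr = mpr, ischemic = ischemic)
  structure(out, class = c("segment_table", "data.frame"),
            territory_calls = terr_calls,
            patient_call = any(terr_calls), threshold = threshold)
}

#' Territory and patient calls of a segment table
#'
#' @param st a `segment_table`.
#' @return List with `territories` (named logical) and `patient` (logical).
#' @export
ischemia_calls <- function(st) {
  stopifnot(inherits(st, "segment_table"))
  list(territories = attr(st, "territory_calls"),
       patient = attr(st, "patient_call"))
}

#' @export
print.segment_table <- function(x, digits = 3, ...) {
  cat("AHA 16-segment perfusion summary (MPR threshold",
      attr(x, "threshold"), ")\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  tc <- attr(x, "territory_calls")
  cat("territories:",
      paste(names(tc), ifelse(tc, "POSITIVE", "negative"), sep = ": ",
            collapse = ", "), "\n")
  cat("patient:", if (attr(x, "patient_call")) "POSITIVE" else "negative",
      "\n")
  invisible(x)
}

#' Write a segment table as CSV
#'
#' Columns: `segment, territory, mbf_stress, mbf_rest, mpr, ischemic`.
#'
#' @param st a `segment_table`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_segment_table <- function(st, path) {
  utils::write.csv(as.data.frame(st), path, row.names = FALSE)
  invisible(path)
}
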