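#' Circular contour set
#'
#' Convenience constructor for a contour set of concentric circles, e.g. to
#' supply manual overrides or ground-truth geometry.
#'
#' @param center LV center (row, col).
#' @param endo_radius,epi_radius radii in pixels.
#' @param n_slices number of slices (same geometry on each).
#' @param reference_angle segment-1 boundary angle (degrees).
#' @param n_vertices polygon vertices.
#' @return A `contour_set`.
#' @export
circle_contours <- function(center, endo_radius, epi_radius, n_slices = 3,
                            reference_angle = 90, n_vertices = 360) {
  theta <- (seq_len(n_vertices) - 1) * 2 * pi / n_vertices
  circ <- function(r) cbind(row = center[1] - r * sin(theta),
                            col = center[2] + r * cos(theta))
  one <- list(endo = circ(endo_radius), epi = circ(epi_radius),
              center = center, reference_angle = reference_angle,
              source = "manual")
  structure(rep(list(one), n_slices), class = "contour_set")
}

#' Pipeline configuration
#'
#' Options of the end-to-end quantification pipeline ([run_pipeline()]).
#'
#' @param dilution pre-bolus dilution correction factor.
#' @param min_quality AIF quality-control threshold ([qc_aif()]).
#' @param n_baseline pre-contrast frames used for baselines.
#' @param stat per-segment summary statistic (`"median"` or `"mean"`).
#' @param mpr_order `"segment"` (ratio of segment MBF summaries) or
#'   `"pixel"` (summary of per-pixel ratios).
#' @param threshold MPR ischemia threshold (strict `<`).
#' @param min_ischemic_segments segments required to call a territory.
#' @param flow_scale MBF reporting scale (60: 1/s to mL/g/min-equivalent).
#' @param register run motion correction (disable for registered input).
#' @param pre_smooth 3x3 Gaussian pre-smoothing before pixel fits.
#' @param slice_roles roles of the 3 slices.
#' @param reference_angle segment-1 boundary angle (degrees).
#' @param blood_shrink endocardial polygon shrink factor for the blood-pool
#'   mask (partial-volume guard).
#' @param seed integer seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(dilution = 10, min_quality = 5, n_baseline = 5,
                            stat = "median", mpr_order = "segment",
                            threshold = 1.5, min_ischemic_segments = 1,
                            flow_scale = 60, register = TRUE,
                            pre_smooth = FALSE,
                            slice_roles = c("basal", "mid", "apical"),
                            reference_angle = 90, blood_shrink = 0.6,
                            seed = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path YAML (or JSON) file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                           simplifyVector = TRUE)
          else yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown pipeline configuration field(s): ",
         paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

blood_pool_mask_from_contours <- function(contours, dims, shrink = 0.6) {
  mask <- array(FALSE, c(dims[1], dims[2], length(contours)))
  rr <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  for (s in seq_along(contours)) {
    cs <- contours[[s]]
    poly <- sweep(sweep(cs$endo, 2, cs$center) * shrink, 2, cs$center, "+")
    mask[, , s] <- matrix(point_in_polygon(as.vector(rr), as.vector(cc),
                                           poly), dims[1], dims[2])
  }
  mask
}

#' Run the full quantitative perfusion pipeline
#'
#' Stages, in order: affine motion correction of the stress, rest and
#' pre-bolus series; contour delineation on the stress temporal MIP (or the
#' supplied override); AHA 16-segment mapping; dual-bolus AIF extraction
#' and quality control; pixel-wise Fermi-constrained deconvolution of the
#' stress and rest series; per-segment MBF/MPR summary with ischemia,
#' territory and patient calls. A failed AIF QC short-circuits to status
#' `"quantification-failed"` with no MBF output, mirroring real dual-bolus
#' failures. With `out_dir` set, all artifacts plus a machine-readable log
#' are written; identical inputs, config and seed give identical outputs.
#'
#' @param stress,rest,prebolus [dynamic_series()] objects or NIfTI paths
#'   readable by [read_series()].
#' @param contours optional contour override: a `contour_set` (or list with
#'   `NULL` entries for slices to keep automatic) or a JSON path.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return Object of class `perf_result`: `status` (`"ok"` or
#'   `"quantification-failed"`), `aif`, `qc`, `contours`, `segment_map`,
#'   `stress_map`, `rest_map`, `segments` (a `segment_table`),
#'   `territory_calls`, `patient_call`, `transforms`, `log`.
#' @export
run_pipeline <- function(stress, rest, prebolus, contours = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, status, detail = "") {
    log[[length(log) + 1]] <<- list(stage = stage, status = status,
                                    detail = detail)
  }
  load_s <- function(x) if (inherits(x, "dynamic_series")) x
                        else read_series(x)
  stress <- load_s(stress); rest <- load_s(rest); prebolus <- load_s(prebolus)

  run <- function() {
    stage <- "motion"
    result <- tryCatch({
      if (config$register) {
        mc_stress <- register_series(stress)
        mc_rest <- register_series(rest)
        mc_pre <- register_series(prebolus)
      } else {
        idtf <- NULL
        mc_stress <- list(corrected = stress, transforms = idtf)
        mc_rest <- list(corrected = rest, transforms = idtf)
        mc_pre <- list(corrected = prebolus, transforms = idtf)
      }
      note(stage, "ok")

      stage <- "contours"
      auto <- delineate_series(mc_stress$corrected,
                               reference_angle = config$reference_angle)
      cset <- if (is.null(contours)) auto
              else override_contours(auto, contours)
      note(stage, "ok",
           paste(vapply(cset, `[[`, "", "source"), collapse = ","))

      stage <- "segments"
      segmap <- build_segment_map(cset, config$slice_roles,
                                  dims = dim(stress$data)[1:2])
      note(stage, "ok")

      stage <- "aif"
      bmask <- blood_pool_mask_from_contours(cset, dim(stress$data)[1:2],
                                             config$blood_shrink)
      aif <- extract_aif(mc_pre$corrected, bmask,
                         dilution = config$dilution,
                         n_baseline = config$n_baseline)
      qc <- qc_aif(aif, config$min_quality)
      if (!qc$pass) {
        note(stage, "quantification-failed",
             sprintf("AIF quality %.3g below threshold %g", qc$quality,
                     qc$min_quality))
        return(structure(list(
          status = "quantification-failed", aif = aif, qc = qc,
          contours = cset, segment_map = segmap, stress_map = NULL,
          rest_map = NULL, segments = NULL, territory_calls = NULL,
          patient_call = NULL,
          transforms = list(stress = mc_stress$transforms,
                            rest = mc_rest$transforms,
                            prebolus = mc_pre$transforms),
          config = config, log = log), class = "perf_result"))
      }
      note(stage, "ok", sprintf("quality %.3g", qc$quality))

      stage <- "pixelwise"
      myo <- segmap$labels > 0
      stress_map <- pixelwise_mbf(mc_stress$corrected, aif, myo,
                                  n_baseline = config$n_baseline,
                                  pre_smooth = config$pre_smooth,
                                  flow_scale = config$flow_scale)
      rest_map <- pixelwise_mbf(mc_rest$corrected, aif, myo,
                                n_baseline = config$n_baseline,
                                pre_smooth = config$pre_smooth,
                                flow_scale = config$flow_scale)
      note(stage, "ok")

      stage <- "summary"
      segs <- segment_summary(stress_map, rest_map, segmap,
                              stat = config$stat,
                              mpr_order = config$mpr_order,
                              threshold = config$threshold,
                              min_ischemic_segments =
                                config$min_ischemic_segments)
      note(stage, "ok")
      structure(list(
        status = "ok", aif = aif, qc = qc, contours = cset,
        segment_map = segmap, stress_map = stress_map,
        rest_map = rest_map, segments = segs,
        territory_calls = attr(segs, "territory_calls"),
        patient_call = attr(segs, "patient_call"),
        transforms = list(stress = mc_stress$transforms,
                          rest = mc_rest$transforms,
                          prebolus = mc_pre$transforms),
        config = config, log = log), class = "perf_result")
    }, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    result
  }
  result <- with_seed(config$seed, run())
  if (!is.null(out_dir)) write_results(result, out_dir)
  result
}

#' @export
print.perf_result <- function(x, ...) {
  cat("<perf_result> status:", x$status, "\n")
  if (x$status == "ok") {
    tc <- x$territory_calls
    cat("  patient:", if (x$patient_call) "POSITIVE" else "negative",
        "| territories:",
        paste(names(tc), ifelse(tc, "+", "-"), collapse = " "), "\n")
    isch <- x$segments$segment[which(x$segments$ischemic)]
    cat("  ischemic segments:",
        if (length(isch)) paste(isch, collapse = " ") else "none", "\n")
  } else {
    cat("  AIF quality", format(x$qc$quality, digits = 3),
        "< threshold", x$qc$min_quality, "- no MBF output\n")
  }
  invisible(x)
}

#' Write pipeline results to a directory
#'
#' Emits `summary.json` (status, calls, QC), `segment_table.csv`,
#' `mbf_stress.nii.gz` / `mbf_rest.nii.gz`, `contours.json`,
#' per-series transform CSVs and `log.json`.
#'
#' @param result a `perf_result`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    status = result$status,
    qc = list(pass = result$qc$pass,
              quality = if (is.finite(result$qc$quality))
                result$qc$quality else "Inf",
              min_quality = result$qc$min_quality),
    patient_call = result$patient_call,
    territory_calls = as.list(result$territory_calls))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(unclass(result$log), file.path(out_dir, "log.json"),
                       auto_unbox = TRUE)
  if (!is.null(result$contours))
    write_contours(result$contours, file.path(out_dir, "contours.json"))
  for (nm in names(result$transforms)) {
    tf <- result$transforms[[nm]]
    if (!is.null(tf))
      utils::write.csv(tf, file.path(out_dir,
                                     paste0("transforms_", nm, ".csv")),
                       row.names = FALSE)
  }
  if (result$status == "ok") {
    write_segment_table(result$segments,
                        file.path(out_dir, "segment_table.csv"))
    RNifti::writeNifti(RNifti::asNifti(result$stress_map$mbf,
                                       datatype = "double"),
                       file.path(out_dir, "mbf_stress.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(result$rest_map$mbf,
                                       datatype = "double"),
                       file.path(out_dir, "mbf_rest.nii.gz"))
  }
  invisible(out_dir)
}
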