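#' Coronary territory of each AHA segment
#'
#' Fixed 16-segment territory lookup for the 3-slice short-axis protocol:
#' LAD = \{1, 2, 7, 8, 13, 14\}, RCA = \{3, 4, 9, 10, 15\},
#' LCX = \{5, 6, 11, 12, 16\}.
#'
#' @return Character vector of length 16 with values "LAD", "RCA", "LCX".
#' @export
segment_territories <- function() {
  c("LAD", "LAD", "RCA", "RCA", "LCX", "LCX",
    "LAD", "LAD", "RCA", "RCA", "LCX", "LCX",
    "LAD", "LAD", "RCA", "LCX")
}

# Sector label for pixel angles (degrees CCW from +col axis, row axis up),
# counted counter-clockwise from the reference angle.
sector_of_angle <- function(theta, reference_angle, n_sectors) {
  rel <- (theta - reference_angle) %% 360
  as.integer(pmin(floor(rel / (360 / n_sectors)), n_sectors - 1)) + 1L
}

# AHA 16-segment label map for one slice role given annulus geometry.
# Returns an integer matrix (0 = outside myocardium).
slice_segment_labels <- function(nr, nc, center, endo, epi, reference_angle,
                                 role = c("basal", "mid", "apical")) {
  role <- match.arg(role)
  n_sectors <- if (role == "apical") 4L else 6L
  base <- switch(role, basal = 0L, mid = 6L, apical = 12L)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dr <- rr - center[1]
  dc <- cc - center[2]
  rad <- sqrt(dr^2 + dc^2)
  theta <- atan2(-dr, dc) * 180 / pi
  lab <- matrix(0L, nr, nc)
  myo <- rad >= endo & rad < epi
  lab[myo] <- base + sector_of_angle(theta[myo], reference_angle, n_sectors)
  lab
}

#' Phantom configuration
#'
#' Describes the synthetic first-pass perfusion acquisition: 3 short-axis
#' slices of an annular left-ventricular myocardium around a blood-pool
#' disc, 120 dynamics per slice at 1.9 mm pixels by default, a gamma-variate
#' main bolus plus a 1:10 diluted pre-bolus, per-segment Fermi kinetics with
#' known myocardial blood flow, additive Gaussian noise, optional per-frame
#' rigid breathing motion and an optional transient subendocardial dark-rim
#' artifact.
#'
#' @param n_slices number of slices; only the 3-slice (16-segment) protocol
#'   is supported.
#' @param n_frames dynamics per slice.
#' @param frame_interval frame spacing (s).
#' @param matrix_size image matrix (pixels, square).
#' @param pixel_size pixel edge (mm).
#' @param endo_radius,epi_radius endo-/epicardial radii (pixels);
#'   `0 < endo < epi < matrix_size / 2` is required.
#' @param mbf_stress,mbf_rest true per-segment myocardial blood flow in
#'   mL/g/min; scalar or length-16 vector (segments 1..16).
#' @param k_stress,tau0_stress,td_stress Fermi decay rate (1/s), shoulder
#'   width (s) and arrival delay (s) under stress.
#' @param k_rest,tau0_rest,td_rest idem at rest.
#' @param aif an [aif_params()] object for the main bolus.
#' @param prebolus_dilution main:pre-bolus dose ratio (10 for the
#'   0.075 / 0.0075 mmol/kg dual-bolus protocol).
#' @param baseline_blood,baseline_myo,baseline_bg pre-contrast signal levels.
#' @param noise_sd additive Gaussian noise SD (signal units).
#' @param prebolus_noise_sd noise SD for the pre-bolus series only
#'   (default: `noise_sd`); raise it to emulate a low-quality diluted
#'   pre-bolus that fails AIF quality control.
#' @param motion_amplitude peak breathing translation (pixels; 0 disables).
#' @param motion_period breathing period (s).
#' @param dark_rim,dark_rim_factor enable the transient dark-rim artifact (a
#'   multiplicative signal drop in the innermost 1-pixel subendocardial ring
#'   during the 5 frames around the main-bolus peak) and its factor.
#' @param reference_angle angle (degrees, CCW from the +col axis with the
#'   row axis pointing up) of the segment-1 boundary; 90 puts the anterior
#'   RV-insertion reference at 12 o'clock.
#' @param seed integer seed for the noise; identical seeds give bit-identical
#'   phantoms.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_slices = 3, n_frames = 120, frame_interval = 1,
                           matrix_size = 128, pixel_size = 1.9,
                           endo_radius = 8, epi_radius = 14,
                           mbf_stress = 3.0, mbf_rest = 1.0,
                           k_stress = 0.3, tau0_stress = 6, td_stress = 2,
                           k_rest = 0.15, tau0_rest = 8, td_rest = 2,
                           aif = aif_params(), prebolus_dilution = 10,
                           baseline_blood = 20, baseline_myo = 15,
                           baseline_bg = 5,
                           noise_sd = 2, prebolus_noise_sd = NULL,
                           motion_amplitude = 0,
                           motion_period = 5,
                           dark_rim = FALSE, dark_rim_factor = 0.6,
                           reference_angle = 90, seed = NULL) {
  if (n_slices != 3)
    stop("only the 3-slice, 16-segment protocol is supported")
  if (!(endo_radius > 0 && endo_radius < epi_radius &&
        epi_radius < matrix_size / 2))
    stop("radii must satisfy 0 < endo < epi < matrix_size / 2")
  if (n_frames < 2) stop("need at least 2 frames")
  expand16 <- function(x, what) {
    if (length(x) == 1) rep(x, 16)
    else if (length(x) == 16) x
    else stop("'", what, "' must be scalar or length 16")
  }
  structure(list(
    n_slices = 3L, n_frames = as.integer(n_frames),
    frame_interval = frame_interval, matrix_size = as.integer(matrix_size),
    pixel_size = pixel_size, endo_radius = endo_radius,
    epi_radius = epi_radius,
    mbf_stress = expand16(mbf_stress, "mbf_stress"),
    mbf_rest = expand16(mbf_rest, "mbf_rest"),
    k_stress = k_stress, tau0_stress = tau0_stress, td_stress = td_stress,
    k_rest = k_rest, tau0_rest = tau0_rest, td_rest = td_rest,
    aif = aif, prebolus_dilution = prebolus_dilution,
    baseline_blood = baseline_blood, baseline_myo = baseline_myo,
    baseline_bg = baseline_bg, noise_sd = noise_sd,
    prebolus_noise_sd = if (is.null(prebolus_noise_sd)) noise_sd
                        else prebolus_noise_sd,
    motion_amplitude = motion_amplitude, motion_period = motion_period,
    dark_rim = dark_rim, dark_rim_factor = dark_rim_factor,
    reference_angle = reference_angle, seed = seed), class = "phantom_config")
}

# Fermi parameters realizing a target MBF (mL/g/min) as h(0) on a per-second
# time axis: h(0) = F / (1 + exp(-k * tau0)) = MBF / 60.
fermi_params_for_mbf <- function(mbf_ml_g_min, k, tau0, td) {
  fermi_params(F = mbf_ml_g_min / 60 * (1 + exp(-k * tau0)),
               k = k, tau0 = tau0, td = td)
}

#' Generate a stress/rest/pre-bolus perfusion phantom
#'
#' Builds three dynamic series (stress, rest and a 1:10 diluted pre-bolus)
#' with known per-segment flows: every myocardial pixel follows the Fermi
#' forward model of its AHA segment, the central blood-pool disc follows the
#' gamma-variate arterial input, and the ground truth records segment label
#' maps, true MBF/MPR, ischemia and territory status (MPR < 1.5, any-segment
#' rule) and any applied per-frame motion.
#'
#' @param config a [phantom_config()].
#' @return An object of class `perf_phantom`: list with `stress`, `rest`,
#'   `prebolus` ([dynamic_series()] objects), `truth` and `config`.
#' @export
make_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  cfg <- config
  n <- cfg$matrix_size
  times <- (seq_len(cfg$n_frames) - 1) * cfg$frame_interval
  center <- rep((n + 1) / 2, 2)

  roles <- c("basal", "mid", "apical")
  labels <- vapply(roles, function(role)
    slice_segment_labels(n, n, center, cfg$endo_radius, cfg$epi_radius,
                         cfg$reference_angle, role),
    matrix(0L, n, n))
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  rad <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  blood <- rad < cfg$endo_radius

  aif_free <- make_aif(within_baseline_zero(cfg$aif), times)
  tissue_for <- function(mbf, k, tau0, td) {
    t(vapply(seq_len(16), function(s)
      make_tissue_curve(aif_free,
                        fermi_params_for_mbf(mbf[s], k, tau0, td))$values,
      numeric(cfg$n_frames)))
  }
  ts_stress <- tissue_for(cfg$mbf_stress, cfg$k_stress, cfg$tau0_stress,
                          cfg$td_stress)
  ts_rest <- tissue_for(cfg$mbf_rest, cfg$k_rest, cfg$tau0_rest, cfg$td_rest)

  # class index per pixel: 1 = background, 2 = blood pool, 2+s = segment s
  build_series <- function(seg_curves, aif_scale) {
    vals <- rbind(rep(cfg$baseline_bg, cfg$n_frames),
                  cfg$baseline_blood + aif_free$values * aif_scale,
                  cfg$baseline_myo + seg_curves * aif_scale)
    arr <- array(0, c(n, n, 3, cfg$n_frames))
    for (s in 1:3) {
      cls <- matrix(1L, n, n)
      cls[blood] <- 2L
      lab <- labels[, , s]
      cls[lab > 0] <- 2L + lab[lab > 0]
      arr[, , s, ] <- vals[as.vector(cls), ]
    }
    arr
  }
  stress_arr <- build_series(ts_stress, 1)
  rest_arr <- build_series(ts_rest, 1)
  pre_arr <- build_series(ts_stress, 1 / cfg$prebolus_dilution)

  if (cfg$dark_rim) {
    rim <- rad >= cfg$endo_radius & rad < cfg$endo_radius + 1
    pk <- which.max(aif_free$values)
    frames <- intersect((pk - 2):(pk + 2), seq_len(cfg$n_frames))
    for (s in 1:3) for (f in frames) {
      for (a in c("stress_arr", "rest_arr")) {
        tmp <- get(a)
        img <- tmp[, , s, f]
        img[rim] <- img[rim] * cfg$dark_rim_factor
        tmp[, , s, f] <- img
        assign(a, tmp)
      }
    }
  }

  motion <- data.frame(slice = rep(1:3, each = cfg$n_frames),
                       frame = rep(seq_len(cfg$n_frames), 3),
                       t_row = 0, t_col = 0)
  if (cfg$motion_amplitude > 0) {
    ph <- (times - times[1]) / cfg$motion_period * 2 * pi
    for (s in 1:3) {
      t_col <- cfg$motion_amplitude * sin(ph)
      t_row <- 0.6 * cfg$motion_amplitude * sin(ph + 1 + 0.4 * s)
      # frame 1 is the motion-free reference
      t_row <- t_row - t_row[1]
      idx <- motion$slice == s
      motion$t_row[idx] <- t_row
      motion$t_col[idx] <- t_col
      shift_series <- function(arr) {
        for (f in 2:cfg$n_frames) {
          arr[, , s, f] <- affine_warp(arr[, , s, f], diag(2),
                                       c(-t_row[f], -t_col[f]), center)
        }
        arr
      }
      stress_arr <- shift_series(stress_arr)
      rest_arr <- shift_series(rest_arr)
      pre_arr <- shift_series(pre_arr)
    }
  }

  if (cfg$noise_sd > 0 || cfg$prebolus_noise_sd > 0) {
    with_seed(cfg$seed, {
      if (cfg$noise_sd > 0) {
        stress_arr <- stress_arr + stats::rnorm(length(stress_arr),
                                                sd = cfg$noise_sd)
        rest_arr <- rest_arr + stats::rnorm(length(rest_arr),
                                            sd = cfg$noise_sd)
      }
      if (cfg$prebolus_noise_sd > 0)
        pre_arr <- pre_arr + stats::rnorm(length(pre_arr),
                                          sd = cfg$prebolus_noise_sd)
    })
  }

  terr <- segment_territories()
  mpr <- cfg$mbf_stress / cfg$mbf_rest
  isch <- mpr < 1.5
  terr_status <- vapply(c("LAD", "RCA", "LCX"),
                        function(v) any(isch[terr == v]), logical(1))
  myo_mask <- labels > 0
  truth <- list(
    segment_labels = labels,
    blood_mask = array(rep(blood, 3), c(n, n, 3)),
    myo_mask = myo_mask,
    mbf_stress = cfg$mbf_stress, mbf_rest = cfg$mbf_rest,
    mpr = mpr, ischemic = isch, territory = terr,
    territory_status = terr_status,
    patient_status = any(terr_status),
    motion = motion,
    aif = aif_free,
    tissue_stress = ts_stress, tissue_rest = ts_rest,
    center = center, endo_radius = cfg$endo_radius,
    epi_radius = cfg$epi_radius, reference_angle = cfg$reference_angle)

  structure(list(
    stress = dynamic_series(stress_arr, times, cfg$pixel_size),
    rest = dynamic_series(rest_arr, times, cfg$pixel_size),
    prebolus = dynamic_series(pre_arr, times, cfg$pixel_size),
    truth = truth, config = cfg), class = "perf_phantom")
}

within_baseline_zero <- function(aifp) {
  aifp$baseline <- 0
  aifp
}

#' @export
print.perf_phantom <- function(x, ...) {
  cat(sprintf(
    "<perf_phantom> %d x %d px, 3 slices, %d frames; true MPR range [%.2f, %.2f]; patient %s\n",
    x$config$matrix_size, x$config$matrix_size, x$config$n_frames,
    min(x$truth$mpr), max(x$truth$mpr),
    if (x$truth$patient_status) "positive" else "negative"))
  invisible(x)
}

#' Simulate per-patient reader calls with known operating characteristics
#'
#' Draws a Bernoulli disease truth at the given prevalence and reader calls
#' at the given sensitivity/specificity, reproducibly by seed. Used to
#' emulate reader-study call tables for the diagnostic-accuracy statistics.
#'
#' @param n_patients number of patients.
#' @param prevalence,sens,spec fractions in `[0, 1]`.
#' @param seed integer seed (optional).
#' @return `data.frame` with columns `patient_id`, `truth`, `call` (0/1).
#' @export
make_reader_calls <- function(n_patients, prevalence, sens, spec,
                              seed = NULL) {
  fr <- c(prevalence = prevalence, sens = sens, spec = spec)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  with_seed(seed, {
    truth <- stats::rbinom(n_patients, 1, prevalence)
    call_pos <- stats::rbinom(n_patients, 1, sens)
    call_neg <- stats::rbinom(n_patients, 1, 1 - spec)
    data.frame(patient_id = seq_len(n_patients), truth = truth,
               call = ifelse(truth == 1, call_pos, call_neg))
  })
}
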