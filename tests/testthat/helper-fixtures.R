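# Shared fixtures, built lazily and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# compact noiseless phantom used by contour/quant/pipeline tests
small_clean_phantom <- function() {
  fixture("small_clean", make_phantom(phantom_config(
    noise_sd = 0, n_frames = 60, matrix_size = 64,
    endo_radius = 7, epi_radius = 12)))
}

lad_phantom <- function() {
  mbf_s <- rep(3, 16)
  mbf_s[7] <- 1.2  # mid anterior, LAD territory
  fixture("pipe_lad", make_phantom(phantom_config(
    noise_sd = 0, n_frames = 60, matrix_size = 64,
    endo_radius = 7, epi_radius = 12, mbf_stress = mbf_s)))
}

lad_result <- function() {
  fixture("pipe_lad_res", run_pipeline(
    lad_phantom()$stress, lad_phantom()$rest, lad_phantom()$prebolus,
    config = pipeline_config(register = FALSE)))
}

degraded_phantom <- function() {
  fixture("degraded", make_phantom(phantom_config(
    n_frames = 60, matrix_size = 64, endo_radius = 7, epi_radius = 12,
    prebolus_dilution = 200, prebolus_noise_sd = 20, noise_sd = 2,
    seed = 42)))
}

moving_phantom <- function() {
  fixture("moving40", make_phantom(phantom_config(
    noise_sd = 0, motion_amplitude = 4, n_frames = 40)))
}

moving_corrected <- function() {
  fixture("moving40_mc", register_series(moving_phantom()$stress))
}

# uniform time grid + gamma-variate AIF used by curve-level tests
test_times <- function() seq(0, 90, by = 1)

test_aif <- function() {
  fixture("aif", make_aif(aif_params(amplitude = 1, onset = 8, alpha = 3,
                                     beta = 2.5), test_times()))
}

# independently coded double-loop discrete convolution (oracle)
brute_conv <- function(aif_values, times, fp) {
  n <- length(times)
  dt <- times[2] - times[1]
  ca <- approx(times, aif_values, xout = times - fp$td, yleft = 0,
               rule = 2)$y
  h <- fp$F / (1 + exp(fp$k * ((seq_len(n) - 1) * dt - fp$tau0)))
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(i)) acc <- acc + ca[j] * h[i - j + 1]
    out[i] <- dt * acc
  }
  out
}

radii_of <- function(poly, center) {
  sqrt((poly[, 1] - center[1])^2 + (poly[, 2] - center[2])^2)
}
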