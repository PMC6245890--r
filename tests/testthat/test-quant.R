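test_that("dual-bolus AIF extraction inverts the 1:10 dilution exactly on the noiseless phantom", {
  ph <- small_clean_phantom()
  aif <- extract_aif(ph$prebolus, ph$truth$blood_mask)
  expect_equal(aif$dilution, 10)  # 0.075 / 0.0075 dose ratio
  expect_lt(max(abs(aif$values - ph$truth$aif$values)), 1e-9)
  expect_equal(aif$arrival_time,
               ph$stress$times[which(ph$truth$aif$values > 0)[1]])
  expect_error(extract_aif(ph$prebolus, ph$truth$blood_mask & FALSE),
               "empty")
})

test_that("a contrast-free pre-bolus is flagged: no arrival, zero quality", {
  arr <- array(7, c(8, 8, 1, 20))
  series <- dynamic_series(arr, 0:19)
  mask <- array(TRUE, c(8, 8, 1))
  aif <- extract_aif(series, mask)
  expect_true(is.na(aif$arrival_time))
  expect_equal(aif$quality, 0)
  expect_false(qc_aif(aif)$pass)
})

test_that("AIF quality control separates clean from degraded pre-boluses", {
  ph <- small_clean_phantom()
  clean <- extract_aif(ph$prebolus, ph$truth$blood_mask)
  expect_true(qc_aif(clean)$pass)
  # degraded: over-diluted and noisy, quality < 5 by construction
  bad_ph <- degraded_phantom()
  bad <- extract_aif(bad_ph$prebolus, bad_ph$truth$blood_mask)
  expect_lt(bad$quality, 5)
  expect_false(qc_aif(bad)$pass)
  expect_true(qc_aif(bad, min_quality = 0)$pass)
})

test_that("Fermi deconvolution recovers h(0) from its own forward model", {
  aif <- test_aif()
  # zero tissue: zero flow
  fit0 <- fermi_deconvolve(aif, rep(0, length(test_times())))
  expect_equal(fit0$mbf, 0)
  # noiseless round trip within 1%
  fp <- fermi_params(1, 0.3, 6, 2)
  y <- make_tissue_curve(aif, fp)$values
  fit <- fermi_deconvolve(aif, y)
  expect_lt(abs(fit$mbf - fermi_mbf(fp)) / fermi_mbf(fp), 0.01)
  expect_true(fit$converged)
  # constant impulse response limit: h = F/2
  y2 <- make_tissue_curve(aif, fermi_params(2, 0, 0))$values
  fit2 <- fermi_deconvolve(aif, y2)
  expect_lt(abs(fit2$mbf - 1) / 1, 0.01)
  expect_error(fermi_deconvolve(aif, c(y[-1], NaN)), "finite")
})

test_that("fermi_fit behaves like a classed model object", {
  aif <- test_aif()
  fp <- fermi_params(1.5, 0.25, 5, 1)
  y <- make_tissue_curve(aif, fp)$values
  fit <- fermi_deconvolve(aif, y, flow_scale = 60)
  expect_s3_class(fit, "fermi_fit")
  expect_named(coef(fit), c("F", "k", "tau0", "td"))
  expect_equal(length(fitted(fit)), length(y))
  expect_equal(fitted(fit)[fit$window] + residuals(fit),
               y[fit$window], tolerance = 1e-8)
  expect_equal(predict(fit), fitted(fit))
  pred <- predict(fit, times = test_times())
  expect_equal(pred, fitted(fit), tolerance = 1e-6)
  expect_output(print(fit), "MBF")
  expect_output(print(summary(fit)), "residual RMS")
  expect_equal(fit$mbf, 60 * unname(
    coef(fit)["F"] / (1 + exp(-coef(fit)["k"] * coef(fit)["tau0"]))))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("MBF and MPR are invariant to a common signal rescaling", {
  aif <- test_aif()
  y <- make_tissue_curve(aif, fermi_params(1, 0.3, 6, 2))$values
  f1 <- fermi_deconvolve(aif, y)
  aif_c <- sampled_curve(test_times(), aif$values * 3.7)
  f2 <- fermi_deconvolve(aif_c, y * 3.7)
  expect_lt(abs(f2$mbf - f1$mbf) / f1$mbf, 1e-6)
})

test_that("pixel-wise maps reproduce segment flows on the noiseless phantom", {
  ph <- small_clean_phantom()
  aif <- extract_aif(ph$prebolus, ph$truth$blood_mask)
  # one slice keeps the runtime modest; all segments of that slice covered
  mask <- ph$truth$myo_mask
  mask[, , c(1, 3)] <- FALSE
  pm <- pixelwise_mbf(ph$stress, aif, mask)
  vals <- pm$mbf[mask]
  truth <- ph$truth$mbf_stress[ph$truth$segment_labels[mask]]
  relerr <- abs(vals - truth) / truth
  expect_gte(mean(relerr < 0.01), 0.99)
  expect_true(all(pm$converged[mask]))
  expect_warning(pixelwise_mbf(ph$stress, aif, mask & FALSE), "empty")
})

test_that("median MBF error stays within 10% at peak-SNR 20", {
  aif <- test_aif()
  fp <- fermi_params(1, 0.3, 6, 2)
  clean <- make_tissue_curve(aif, fp)$values
  sigma <- max(clean) / 20
  errs <- withr::with_seed(77, vapply(1:30, function(i) {
    fit <- fermi_deconvolve(aif, clean + rnorm(length(clean), sd = sigma))
    abs(fit$mbf - fermi_mbf(fp)) / fermi_mbf(fp)
  }, 0))
  expect_lte(median(errs), 0.10)
})

test_that("segment summary computes MPR, strict-threshold ischemia and territory calls", {
  lab <- small_clean_phantom()$truth$segment_labels
  segmap <- structure(list(labels = lab,
                           territories = data.frame(
                             segment = 1:16,
                             territory = segment_territories())),
                      class = "segment_map")
  mk_map <- function(per_segment) {
    arr <- array(NA_real_, dim(lab))
    arr[lab > 0] <- per_segment[lab[lab > 0]]
    structure(list(mbf = arr, rss = arr * 0,
                   converged = !is.na(arr) & lab > 0, mask = lab > 0,
                   flow_scale = 60, n_failed = 0L), class = "mbf_map")
  }
  # uniform MPR 3: nothing ischemic
  st <- segment_summary(mk_map(rep(3, 16)), mk_map(rep(1, 16)), segmap)
  expect_equal(st$mpr, rep(3, 16))
  expect_false(any(st$ischemic))
  expect_false(attr(st, "patient_call"))
  # one LAD segment at 1.4: segment, territory and patient all positive
  stress <- rep(3, 16); stress[2] <- 1.4
  st2 <- segment_summary(mk_map(stress), mk_map(rep(1, 16)), segmap)
  expect_true(st2$ischemic[2])
  expect_equal(sum(st2$ischemic), 1)
  expect_equal(attr(st2, "territory_calls"),
               c(LAD = TRUE, RCA = FALSE, LCX = FALSE))
  expect_true(attr(st2, "patient_call"))
  # MPR exactly 1.5 is NOT ischemic (strict inequality)
  stress15 <- rep(3, 16); stress15[5] <- 1.5
  st3 <- segment_summary(mk_map(stress15), mk_map(rep(1, 16)), segmap)
  expect_false(st3$ischemic[5])
  expect_false(attr(st3, "patient_call"))
  # non-positive rest flow: indeterminate, excluded with a warning
  rest0 <- rep(1, 16); rest0[7] <- 0
  expect_warning(st4 <- segment_summary(mk_map(rep(3, 16)), mk_map(rest0),
                                        segmap), "indeterminate")
  expect_true(is.na(st4$mpr[7]))
  expect_true(is.na(st4$ischemic[7]))
  # min_ischemic_segments raises the bar for a territory call
  st5 <- segment_summary(mk_map(stress), mk_map(rep(1, 16)), segmap,
                         min_ischemic_segments = 2)
  expect_false(attr(st5, "patient_call"))
})
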