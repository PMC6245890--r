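test_that("noiseless myocardial pixels follow their segment's forward model exactly", {
  ph <- small_clean_phantom()
  cfg <- ph$config
  lab <- ph$truth$segment_labels
  for (seg in c(1, 8, 15)) {
    sl <- if (seg <= 6) 1 else if (seg <= 12) 2 else 3
    idx <- which(lab[, , sl] == seg, arr.ind = TRUE)[1, ]
    tc <- ph$stress$data[idx[1], idx[2], sl, ] - cfg$baseline_myo
    expect_equal(tc, ph$truth$tissue_stress[seg, ], tolerance = 1e-12)
  }
  # blood pool follows the AIF
  ctr <- ph$truth$center
  blood <- ph$stress$data[ctr[1] - 0.5, ctr[2] - 0.5, 2, ] -
    cfg$baseline_blood
  expect_equal(blood, ph$truth$aif$values, tolerance = 1e-12)
})

test_that("3-slice phantom carries exactly the 16 AHA segments in role order", {
  ph <- small_clean_phantom()
  lab <- ph$truth$segment_labels
  expect_setequal(unique(as.vector(lab[lab > 0])), 1:16)
  expect_setequal(unique(as.vector(lab[, , 1][lab[, , 1] > 0])), 1:6)
  expect_setequal(unique(as.vector(lab[, , 2][lab[, , 2] > 0])), 7:12)
  expect_setequal(unique(as.vector(lab[, , 3][lab[, , 3] > 0])), 13:16)
  expect_error(phantom_config(n_slices = 2), "3-slice")
  expect_error(phantom_config(endo_radius = 10, epi_radius = 8), "radii")
})

test_that("identical seeds reproduce the phantom bit-for-bit, different seeds differ", {
  cfg <- function(s) phantom_config(n_frames = 20, matrix_size = 48,
                                    endo_radius = 6, epi_radius = 10,
                                    noise_sd = 2, seed = s)
  a <- make_phantom(cfg(5))
  b <- make_phantom(cfg(5))
  c <- make_phantom(cfg(6))
  expect_identical(a$stress$data, b$stress$data)
  expect_identical(a$prebolus$data, b$prebolus$data)
  expect_false(identical(a$stress$data, c$stress$data))
})

test_that("pre-bolus blood-pool peak is exactly one tenth of the main bolus peak", {
  ph <- small_clean_phantom()
  cfg <- ph$config
  blood <- ph$truth$blood_mask[, , 1]
  idx <- which(blood, arr.ind = TRUE)[1, ]
  pre <- ph$prebolus$data[idx[1], idx[2], 1, ] - cfg$baseline_blood
  main <- ph$stress$data[idx[1], idx[2], 1, ] - cfg$baseline_blood
  expect_equal(10 * max(pre), max(main), tolerance = 1e-12)
})

test_that("noise- and motion-free mean myocardial signal equals the segment-mean of true curves", {
  ph <- small_clean_phantom()
  cfg <- ph$config
  lab <- ph$truth$segment_labels
  counts <- table(factor(lab[lab > 0], levels = 1:16))
  expected <- cfg$baseline_myo +
    colSums(ph$truth$tissue_stress * as.vector(counts)) / sum(counts)
  flat <- matrix(ph$stress$data, ncol = dim(ph$stress$data)[4])
  observed <- colMeans(flat[as.vector(lab > 0), ])
  expect_equal(observed, expected, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("ground-truth territory and patient status follow the any-segment MPR rule", {
  mbf_s <- rep(3, 16)
  mbf_s[9] <- 1.4  # segment 9 is RCA territory
  ph <- make_phantom(phantom_config(n_frames = 10, matrix_size = 48,
                                    endo_radius = 6, epi_radius = 10,
                                    noise_sd = 0, mbf_stress = mbf_s))
  expect_equal(ph$truth$ischemic, c(rep(FALSE, 8), TRUE, rep(FALSE, 7)))
  expect_equal(unname(ph$truth$territory_status),
               c(FALSE, TRUE, FALSE))  # LAD, RCA, LCX
  expect_true(ph$truth$patient_status)
  # an MPR of exactly 1.5 is not ischemic
  ph2 <- make_phantom(phantom_config(n_frames = 10, matrix_size = 48,
                                     endo_radius = 6, epi_radius = 10,
                                     noise_sd = 0, mbf_stress = 1.5,
                                     mbf_rest = 1))
  expect_false(any(ph2$truth$ischemic))
  expect_false(ph2$truth$patient_status)
})

test_that("reader-call simulation honours its operating characteristics", {
  perfect <- make_reader_calls(200, 0.3, 1, 1, seed = 1)
  expect_identical(perfect$call, perfect$truth)
  a <- make_reader_calls(53, 16 / 53, 0.688, 0.943, seed = 9)
  b <- make_reader_calls(53, 16 / 53, 0.688, 0.943, seed = 9)
  expect_identical(a, b)
  big <- make_reader_calls(1e5, 0.4, 0.688, 0.943, seed = 2)
  expect_lt(abs(mean(big$call[big$truth == 1]) - 0.688), 0.005)
  expect_lt(abs(mean(1 - big$call[big$truth == 0]) - 0.943), 0.005)
  expect_error(make_reader_calls(10, 1.2, 0.5, 0.5), "\\[0, 1\\]")
})
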