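test_that("temporal MIP takes per-pixel maxima and is idempotent", {
  arr <- array(0, c(2, 2, 1, 3))
  arr[1, 1, 1, ] <- c(1, 5, 2)
  arr[2, 1, 1, ] <- c(0, 3, 3)
  arr[1, 2, 1, ] <- c(4, 9, 1)
  arr[2, 2, 1, ] <- c(2, 2, 2)
  mip <- temporal_mip(dynamic_series(arr, 0:2))
  expect_equal(mip[, , 1], matrix(c(5, 3, 9, 2), 2, 2))
  # monotone signal: MIP is the last frame
  inc <- array(rep(1:5, each = 4), c(2, 2, 1, 5))
  expect_equal(temporal_mip(dynamic_series(inc, 0:4))[, , 1],
               inc[, , 1, 5])
  # idempotence: MIP of a single-frame series is itself
  one <- array(mip, c(2, 2, 1, 1))
  expect_equal(temporal_mip(dynamic_series(one, 0))[, , 1], mip[, , 1])
})

test_that("contours recover the phantom annulus to sub-pixel accuracy", {
  ph <- small_clean_phantom()
  mip <- temporal_mip(ph$stress)
  for (s in 1:3) {
    dl <- delineate(mip[, , s])
    expect_lt(max(abs(dl$center - ph$truth$center)), 1)
    expect_lt(mean(abs(radii_of(dl$endo, dl$center) -
                         ph$config$endo_radius)), 1)
    expect_lt(mean(abs(radii_of(dl$epi, dl$center) -
                         ph$config$epi_radius)), 1)
  }
})

test_that("delineation fails cleanly on blank input and translates with the image", {
  expect_error(delineate(matrix(1, 32, 32)), "delineation failed")
  ph <- small_clean_phantom()
  mip <- temporal_mip(ph$stress)[, , 1]
  shifted <- matrix(ph$config$baseline_bg, 64, 64)
  shifted[8:64, 8:64] <- mip[1:57, 1:57]
  a <- delineate(mip)
  b <- delineate(shifted)
  expect_lt(max(abs(b$center - (a$center + 7))), 1)
  expect_lt(mean(abs(radii_of(b$endo, b$center) -
                       radii_of(a$endo, a$center))), 0.5)
})

test_that("manual contours override per slice with nesting validation", {
  ph <- small_clean_phantom()
  auto <- delineate_series(ph$stress)
  expect_identical(override_contours(auto, list(NULL, NULL, NULL)), auto)
  manual <- circle_contours(c(30, 30), 6, 11, n_slices = 1)
  merged <- override_contours(auto, list(NULL, manual[[1]], NULL))
  expect_identical(merged[[1]], auto[[1]])
  expect_identical(merged[[3]], auto[[3]])
  expect_equal(merged[[2]]$source, "manual")
  expect_equal(mean(radii_of(merged[[2]]$endo, c(30, 30))), 6)
  # endo outside epi is rejected
  bad <- list(endo = circle_contours(c(30, 30), 12, 13)[[1]]$endo,
              epi = circle_contours(c(30, 30), 6, 11)[[1]]$epi,
              center = c(30, 30))
  expect_error(override_contours(auto, list(bad, NULL, NULL)),
               "not inside")
})

test_that("segment map partitions the annulus into balanced sectors with fixed territories", {
  cs <- circle_contours(c(32.5, 32.5), 8, 14)
  sm <- build_segment_map(cs, dims = c(64, 64))
  lab <- sm$labels
  # basal/mid sector sizes agree within 2%
  for (s in 1:2) {
    counts <- table(lab[, , s][lab[, , s] > 0])
    expect_lt(diff(range(counts)) / mean(counts), 0.02 * 6)
    expect_equal(length(counts), 6)
  }
  expect_equal(length(table(lab[, , 3][lab[, , 3] > 0])), 4)
  # territories partition 1..16
  terr <- sm$territories
  expect_setequal(terr$segment[terr$territory == "LAD"],
                  c(1, 2, 7, 8, 13, 14))
  expect_setequal(terr$segment[terr$territory == "RCA"],
                  c(3, 4, 9, 10, 15))
  expect_setequal(terr$segment[terr$territory == "LCX"],
                  c(5, 6, 11, 12, 16))
  # every myocardial pixel labeled exactly once, none outside
  between <- lab[, , 1] > 0
  expect_equal(sum(between), sum(lab[, , 1] %in% 1:6))
})

test_that("rotating the reference angle by 60 degrees permutes basal labels cyclically", {
  cs0 <- circle_contours(c(32.5, 32.5), 8, 14)
  cs60 <- circle_contours(c(32.5, 32.5), 8, 14, reference_angle = 150)
  l0 <- build_segment_map(cs0, dims = c(64, 64))$labels[, , 1]
  l60 <- build_segment_map(cs60, dims = c(64, 64))$labels[, , 1]
  sel <- l0 > 0
  # advancing the reference by one sector width shifts every label down by 1
  expect_equal(l60[sel], ifelse(l0[sel] == 1, 6L, l0[sel] - 1L))
})

test_that("segment map coverage matches the contour interior with no gaps", {
  ph <- small_clean_phantom()
  cs <- circle_contours(ph$truth$center, ph$config$endo_radius,
                        ph$config$epi_radius)
  sm <- build_segment_map(cs, dims = c(64, 64))
  # compare against the generator's own label map
  mismatch <- mean((sm$labels > 0) != (ph$truth$segment_labels > 0))
  expect_lt(mismatch, 0.02)
  agree <- sm$labels[sm$labels > 0 & ph$truth$segment_labels > 0] ==
    ph$truth$segment_labels[sm$labels > 0 & ph$truth$segment_labels > 0]
  expect_gt(mean(agree), 0.97)
})

test_that("contours round-trip through JSON", {
  cs <- circle_contours(c(20.25, 21.75), 5.5, 9.25)
  path <- withr::local_tempfile(fileext = ".json")
  write_contours(cs, path)
  back <- read_contours(path)
  expect_equal(back[[1]]$endo, cs[[1]]$endo, tolerance = 1e-12)
  expect_equal(back[[2]]$epi, cs[[2]]$epi, tolerance = 1e-12)
  expect_equal(back[[1]]$center, cs[[1]]$center)
})
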