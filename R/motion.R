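# Affine warp: sample `img` at A (x - center) + center + t for every target
# pixel x = (row, col), bilinear interpolation, edge-value padding.
affine_warp <- function(img, lin, tr, center = (dim(img) + 1) / 2) {
  nr <- nrow(img)
  nc <- ncol(img)
  rr <- matrix(seq_len(nr), nr, nc) - center[1]
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2]
  src_r <- lin[1, 1] * rr + lin[1, 2] * cc + center[1] + tr[1]
  src_c <- lin[2, 1] * rr + lin[2, 2] * cc + center[2] + tr[2]
  matrix(bilinear_sample(img, as.vector(src_r), as.vector(src_c)), nr, nc)
}

par_to_transform <- function(p) {
  list(lin = diag(2) + matrix(p[1:4], 2, 2), tr = p[5:6])
}

#' Detect a region of interest around the heart
#'
#' The ROI of each slice is the bounding box (padded by `pad` pixels, clipped
#' to the image) of the largest connected component of pixels whose temporal
#' standard deviation exceeds the `quantile` quantile of that slice's
#' temporal-SD map. First-pass enhancement makes the heart by far the most
#' temporally variable structure, so this isolates it automatically.
#'
#' @param series a [dynamic_series()] with at least 10 frames.
#' @param pad padding (pixels).
#' @param quantile SD-map quantile defining "highly dynamic" pixels.
#' @return List with one ROI per slice: `list(slice, rows = c(lo, hi),
#'   cols = c(lo, hi))`, 1-based inclusive.
#' @export
detect_roi <- function(series, pad = 5, quantile = 0.95) {
  stopifnot(inherits(series, "dynamic_series"))
  if (n_frames(series) < 10) stop("need at least 10 frames to detect an ROI")
  lapply(seq_len(n_slices(series)), function(s) {
    x <- series$data[, , s, , drop = TRUE]
    nfr <- dim(x)[3]
    mu <- rowMeans(x, dims = 2)
    sdmap <- sqrt(pmax(rowSums((x - as.vector(mu))^2, dims = 2) / (nfr - 1), 0))
    if (max(sdmap) <= 0)
      stop("ROI not found: series is constant in time (slice ", s, ")")
    thr <- stats::quantile(sdmap, quantile)
    mask <- sdmap >= thr & sdmap > 0
    if (!any(mask))
      stop("ROI not found: no pixels above the SD threshold (slice ", s, ")")
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- lab == which.max(sizes)
    idx <- which(keep, arr.ind = TRUE)
    list(slice = s,
         rows = c(max(1, min(idx[, 1]) - pad),
                  min(nrow(mask), max(idx[, 1]) + pad)),
         cols = c(max(1, min(idx[, 2]) - pad),
                  min(ncol(mask), max(idx[, 2]) + pad)))
  })
}

#' Joint correlation of two images within an ROI
#'
#' Pearson correlation of the pixel values of two same-shaped images
#' restricted to the ROI box; the similarity score maximized by the motion
#' correction.
#'
#' @param a,b numeric matrices of identical shape.
#' @param roi an ROI as returned by [detect_roi()] (one slice's entry).
#' @return Correlation in `[-1, 1]`.
#' @export
joint_correlation <- function(a, b, roi) {
  stopifnot(all(dim(a) == dim(b)))
  av <- a[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2]]
  bv <- b[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2]]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("joint correlation undefined: zero variance within ROI")
  stats::cor(as.vector(av), as.vector(bv))
}

# Correlation of warped moving-frame samples (at ROI pixels) with the
# reference values; returns -Inf on degenerate input so the optimizer
# steps away rather than aborting.
roi_warp_cor <- function(p, moving, ref_vals, roi_r, roi_c, center) {
  tf <- par_to_transform(p)
  src_r <- tf$lin[1, 1] * (roi_r - center[1]) +
    tf$lin[1, 2] * (roi_c - center[2]) + center[1] + tf$tr[1]
  src_c <- tf$lin[2, 1] * (roi_r - center[1]) +
    tf$lin[2, 2] * (roi_c - center[2]) + center[2] + tf$tr[2]
  v <- bilinear_sample(moving, src_r, src_c)
  if (stats::sd(v) == 0) return(-Inf)
  stats::cor(v, ref_vals)
}

#' Correct in-plane respiratory motion by affine registration
#'
#' Each frame is registered to the corrected previous dynamic by
#' derivative-free local maximization (Nelder-Mead) of the joint correlation
#' within the slice's automatically detected ROI, over 6 affine parameters
#' (2x2 linear part as a deviation from identity, plus translation), so the
#' optimized parameters are directly the cumulative frame-to-reference
#' (first-frame) transform and per-frame errors do not accumulate. The
#' search is hierarchical: translation first, then the full affine, which
#' is only accepted when it improves the score by at least `improve_tol`
#' (this keeps unidentifiable linear components of a near-circular heart
#' from drifting in); frames improving on the running transform by less
#' than `improve_tol` keep it unchanged. The similarity is evaluated on
#' lightly Gaussian-smoothed copies of the frames (`smooth_sigma`), which
#' suppresses the sub-pixel bias of bilinear resampling; output frames are
#' resampled from the raw data (bilinear, edge-value padding). An optimizer
#' failure on a frame keeps the previous transform with a warning, never an
#' abort.
#'
#' @param series a [dynamic_series()].
#' @param roi optional precomputed ROI list; default [detect_roi()].
#' @param max_eval maximum cost evaluations per frame.
#' @param improve_tol minimum correlation improvement to accept a transform.
#' @param affine_tol minimum additional improvement over the translation
#'   solution to accept the full affine (a stiffer bar for 4 extra degrees
#'   of freedom; bolus-arrival contrast change can otherwise masquerade as
#'   a scale change).
#' @param smooth_sigma Gaussian sigma (pixels) for the similarity images;
#'   0 disables smoothing.
#' @return List of class `motion_correction`: `corrected` (a
#'   [dynamic_series()]) and `transforms` (data.frame with columns `slice`,
#'   `frame`, `a11, a12, a21, a22`, `t_row`, `t_col` of the cumulative
#'   frame-to-reference transforms).
#' @export
register_series <- function(series, roi = NULL, max_eval = 500,
                            improve_tol = 2e-3, affine_tol = 0.02,
                            smooth_sigma = 1) {
  stopifnot(inherits(series, "dynamic_series"))
  if (is.null(roi)) roi <- detect_roi(series)
  smooth_img <- if (smooth_sigma > 0) {
    r <- max(2, ceiling(2 * smooth_sigma))
    gk <- outer(stats::dnorm(-r:r, sd = smooth_sigma),
                stats::dnorm(-r:r, sd = smooth_sigma))
    gk <- gk / sum(gk)
    function(m) as.matrix(EBImage::filter2(m, gk))
  } else identity
  nfr <- n_frames(series)
  nsl <- n_slices(series)
  center <- (dim(series$data)[1:2] + 1) / 2
  out <- series$data
  rows <- list()
  for (s in seq_len(nsl)) {
    rb <- roi[[s]]
    grid <- expand.grid(r = rb$rows[1]:rb$rows[2], c = rb$cols[1]:rb$cols[2])
    roi_r <- grid$r
    roi_c <- grid$c
    prev_par <- rep(0, 6)
    tf_rows <- matrix(0, nfr, 6)
    tf_rows[1, 1:4] <- c(1, 0, 0, 1)
    # each frame is matched against the corrected previous dynamic (already
    # resampled into the reference space), so the optimized parameters ARE
    # the cumulative frame-to-reference transform and per-frame errors do
    # not accumulate through composition
    ref_vals <- smooth_img(series$data[, , s, 1])[cbind(roi_r, roi_c)]
    for (i in 2:nfr) {
      mov <- smooth_img(series$data[, , s, i])
      fit <- tryCatch({
        cost <- function(p) -roi_warp_cor(p, mov, ref_vals, roi_r, roi_c,
                                          center)
        score0 <- -cost(prev_par)
        # translation first: the affine refinement must beat it by more
        # than improve_tol, which keeps unidentifiable linear components
        # (e.g. rotation of a near-circular heart) from drifting in
        opt_t <- stats::optim(prev_par[5:6],
                              function(p) cost(c(prev_par[1:4], p)),
                              method = "Nelder-Mead",
                              control = list(maxit = round(max_eval * 0.4),
                                             reltol = 1e-9))
        opt_a <- stats::optim(c(prev_par[1:4], opt_t$par), cost,
                              method = "Nelder-Mead",
                              control = list(maxit = round(max_eval * 0.6),
                                             reltol = 1e-9,
                                             parscale = c(rep(0.02, 4), 1, 1)))
        if (-opt_a$value - (-opt_t$value) >= affine_tol) opt_a$par
        else if (-opt_t$value - score0 >= improve_tol)
          c(prev_par[1:4], opt_t$par)
        else prev_par
      }, error = function(e) {
        warning("registration failed on slice ", s, " frame ", i,
                "; keeping the previous transform (",
                conditionMessage(e), ")")
        prev_par
      })
      prev_par <- fit
      tf <- par_to_transform(fit)
      if (any(fit != 0)) {
        out[, , s, i] <- affine_warp(series$data[, , s, i], tf$lin, tf$tr,
                                     center)
        ref_vals <- affine_warp(mov, tf$lin, tf$tr,
                                center)[cbind(roi_r, roi_c)]
      } else ref_vals <- mov[cbind(roi_r, roi_c)]
      tf_rows[i, ] <- c(tf$lin[1, 1], tf$lin[1, 2], tf$lin[2, 1],
                        tf$lin[2, 2], tf$tr[1], tf$tr[2])
    }
    rows[[s]] <- data.frame(slice = s, frame = seq_len(nfr),
                            a11 = tf_rows[, 1], a12 = tf_rows[, 2],
                            a21 = tf_rows[, 3], a22 = tf_rows[, 4],
                            t_row = tf_rows[, 5], t_col = tf_rows[, 6])
  }
  structure(list(
    corrected = dynamic_series(out, series$times, series$pixel_size),
    transforms = do.call(rbind, rows), roi = roi),
    class = "motion_correction")
}

#' @export
print.motion_correction <- function(x, ...) {
  disp <- sqrt(x$transforms$t_row^2 + x$transforms$t_col^2)
  cat(sprintf(
    "<motion_correction> %d slices x %d frames; mean |translation| %.3f px, max %.3f px\n",
    length(unique(x$transforms$slice)), max(x$transforms$frame),
    mean(disp), max(disp)))
  invisible(x)
}

#' Write motion-correction transforms as CSV
#'
#' @param mc a `motion_correction` object from [register_series()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_transforms <- function(mc, path) {
  utils::write.csv(mc$transforms, path, row.names = FALSE)
  invisible(path)
}
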