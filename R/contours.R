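#' Temporal maximum intensity projection
#'
#' Per-pixel maximum over all dynamic frames, the high-contrast feature
#' image used for contour delineation.
#'
#' @param series a [dynamic_series()] (or a 3-D `[row, col, frame]` array).
#' @return A `[row, col, slice]` array of per-slice MIP images.
#' @export
temporal_mip <- function(series) {
  arr <- if (inherits(series, "dynamic_series")) series$data else series
  if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr)[1:2], 1L, dim(arr)[3])
  apply(arr, c(1, 2, 3), max)
}

#' Delineate endo- and epicardial contours on a MIP feature image
#'
#' The left-ventricular blood pool is found as the brightest connected
#' component after Otsu thresholding; its centroid is the LV center. The
#' myocardium is then traced on `n_rays` polar rays: on each ray the
#' endocardial edge is the first outward drop below `endo_frac` of the
#' blood-pool intensity and the epicardial edge the subsequent drop below
#' `epi_frac` of the myocardial ring's median intensity. Radial profiles
#' are smoothed with a periodic moving average before the polygons are
#' built.
#'
#' @param mip a single-slice feature image (matrix).
#' @param n_rays number of polar rays.
#' @param endo_frac,epi_frac edge-detection threshold fractions.
#' @param smooth_window smoothing window in degrees.
#' @param reference_angle reference angle (degrees) stored with the contour
#'   for later segment mapping.
#' @return A list (one slice of a contour set): `endo` and `epi` closed
#'   polygons as `n_rays x 2` matrices of (row, col), `center`,
#'   `reference_angle`, and `source = "auto"`.
#' @export
delineate <- function(mip, n_rays = 360, endo_frac = 0.6, epi_frac = 0.4,
                      smooth_window = 15, reference_angle = 90) {
  stopifnot(is.matrix(mip))
  rng <- range(mip)
  if (rng[2] <= rng[1])
    stop("delineation failed: no blood pool found (flat image)")
  img01 <- (mip - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(img01))
  mask <- img01 > thr
  lab <- EBImage::bwlabel(mask)
  ncomp <- max(lab)
  if (ncomp < 1) stop("delineation failed: no blood pool found")
  means <- vapply(seq_len(ncomp), function(i) mean(mip[lab == i]), 0)
  sizes <- tabulate(lab[lab > 0], ncomp)
  cand <- which(sizes >= 5)
  if (length(cand) == 0) stop("delineation failed: no blood pool found")
  comp <- cand[which.max(means[cand])]
  idx <- which(lab == comp, arr.ind = TRUE)
  center <- c(mean(idx[, 1]), mean(idx[, 2]))
  # robust blood-pool reference intensity (upper quartile guards against a
  # component that merged blood pool and myocardium)
  bp_int <- as.numeric(stats::quantile(mip[lab == comp], 0.75))

  theta <- (seq_len(n_rays) - 1) * (360 / n_rays) * pi / 180
  max_r <- min(center[1] - 1, nrow(mip) - center[1],
               center[2] - 1, ncol(mip) - center[2])
  rs <- seq(0.5, max_r, by = 0.25)
  endo_r <- rep(NA_real_, n_rays)
  epi_r <- rep(NA_real_, n_rays)
  prof <- matrix(0, n_rays, length(rs))
  for (j in seq_len(n_rays)) {
    prof[j, ] <- bilinear_sample(mip, center[1] - rs * sin(theta[j]),
                                 center[2] + rs * cos(theta[j]))
    k <- which(prof[j, ] < endo_frac * bp_int)
    if (length(k)) endo_r[j] <- rs[k[1]]
  }
  if (mean(is.na(endo_r)) > 0.25)
    stop("delineation failed: endocardial edge missing on > 25% of rays")
  ring_samples <- unlist(lapply(seq_len(n_rays), function(j) {
    if (is.na(endo_r[j])) return(numeric(0))
    bilinear_sample(mip, center[1] - (endo_r[j] + c(0.5, 1, 1.5, 2)) *
                      sin(theta[j]),
                    center[2] + (endo_r[j] + c(0.5, 1, 1.5, 2)) *
                      cos(theta[j]))
  }))
  ring_med <- stats::median(ring_samples)
  for (j in seq_len(n_rays)) {
    if (is.na(endo_r[j])) next
    beyond <- which(rs > endo_r[j] + 0.5)
    k <- beyond[prof[j, beyond] < epi_frac * ring_med]
    if (length(k)) epi_r[j] <- rs[k[1]]
  }
  if (mean(is.na(epi_r)) > 0.25)
    stop("delineation failed: epicardial edge missing on > 25% of rays")

  fill_periodic <- function(r) {
    if (!anyNA(r)) return(r)
    ok <- which(!is.na(r))
    ang <- seq_len(n_rays)
    stats::approx(c(ok - n_rays, ok, ok + n_rays), rep(r[ok], 3),
                  xout = ang)$y
  }
  win <- max(3, round(smooth_window / (360 / n_rays)))
  endo_r <- periodic_smooth(fill_periodic(endo_r), win)
  epi_r <- periodic_smooth(fill_periodic(epi_r), win)

  poly <- function(r) cbind(row = center[1] - r * sin(theta),
                            col = center[2] + r * cos(theta))
  list(endo = poly(endo_r), epi = poly(epi_r), center = center,
       reference_angle = reference_angle, source = "auto")
}

#' Delineate contours for all slices of a series
#'
#' Runs [temporal_mip()] and [delineate()] on each slice.
#'
#' @param series a [dynamic_series()].
#' @param ... passed to [delineate()].
#' @return An object of class `contour_set`: list of per-slice contour
#'   lists.
#' @export
delineate_series <- function(series, ...) {
  mip <- temporal_mip(series)
  structure(lapply(seq_len(dim(mip)[3]),
                   function(s) delineate(mip[, , s], ...)),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  for (s in seq_along(x)) {
    cat(sprintf(
      "slice %d [%s]: center (%.1f, %.1f), mean endo r %.2f px, mean epi r %.2f px\n",
      s, x[[s]]$source, x[[s]]$center[1], x[[s]]$center[2],
      mean(sqrt(rowSums((x[[s]]$endo - rep(x[[s]]$center,
                                           each = nrow(x[[s]]$endo)))^2))),
      mean(sqrt(rowSums((x[[s]]$epi - rep(x[[s]]$center,
                                          each = nrow(x[[s]]$epi)))^2)))))
  }
  invisible(x)
}

validate_contour_slice <- function(cs) {
  if (is.null(cs$endo) || is.null(cs$epi))
    stop("contour slice must have 'endo' and 'epi' polygons")
  inside <- point_in_polygon(cs$endo[, 1], cs$endo[, 2], cs$epi)
  if (!all(inside))
    stop("invalid contours: endocardial polygon is not inside the ",
         "epicardial polygon")
  invisible(cs)
}

#' Apply manual contour overrides
#'
#' Replaces automatic contours slice-by-slice where a manual contour is
#' provided (operator optimization of the automatic delineation, e.g. to
#' avoid partial-volume effects); other slices keep the automatic result.
#' Overridden slices are flagged `source = "manual"`.
#'
#' @param auto a `contour_set`.
#' @param manual a `contour_set`-like list (entries may be `NULL`), or a
#'   path to a contour JSON file from [write_contours()].
#' @return The merged `contour_set`.
#' @export
override_contours <- function(auto, manual) {
  if (is.character(manual)) manual <- read_contours(manual)
  out <- auto
  for (s in seq_along(manual)) {
    m <- manual[[s]]
    if (is.null(m)) next
    if (is.null(m$center)) m$center <- colMeans(m$endo)
    if (is.null(m$reference_angle))
      m$reference_angle <- auto[[s]]$reference_angle
    m$source <- "manual"
    validate_contour_slice(m)
    out[[s]] <- m
  }
  structure(out, class = "contour_set")
}

#' Build the AHA 16-segment label map from contours
#'
#' Pixels between the endo- and epicardial polygons are partitioned by
#' angle around the LV center, counter-clockwise from the reference angle:
#' 6 equal sectors on the basal (labels 1-6) and mid (7-12) slices, 4 on
#' the apical slice (13-16). Segment-to-territory lookup is the fixed
#' [segment_territories()] map.
#'
#' @param contours a `contour_set` with 3 slices.
#' @param slice_roles roles of the slices, a permutation of
#'   `c("basal", "mid", "apical")`.
#' @param dims image dims (rows, cols); defaults to covering the contours.
#' @return Object of class `segment_map`: list with `labels` (integer
#'   `[row, col, slice]` array, 0 = background) and `territories`
#'   (data.frame segment -> territory).
#' @export
build_segment_map <- function(contours, slice_roles = c("basal", "mid",
                                                        "apical"),
                              dims = NULL) {
  if (length(contours) != 3 ||
      !setequal(slice_roles, c("basal", "mid", "apical")))
    stop("need 3 slices with roles basal, mid, apical")
  if (is.null(dims)) {
    all_pts <- do.call(rbind, lapply(contours, function(cs) cs$epi))
    dims <- c(ceiling(max(all_pts[, 1])) + 1, ceiling(max(all_pts[, 2])) + 1)
  }
  labels <- array(0L, c(dims[1], dims[2], 3))
  rr <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  for (s in 1:3) {
    cs <- contours[[s]]
    validate_contour_slice(cs)
    role <- slice_roles[s]
    n_sectors <- if (role == "apical") 4L else 6L
    base <- switch(role, basal = 0L, mid = 6L, apical = 12L)
    in_epi <- point_in_polygon(as.vector(rr), as.vector(cc), cs$epi)
    in_endo <- point_in_polygon(as.vector(rr), as.vector(cc), cs$endo)
    myo <- matrix(in_epi & !in_endo, dims[1], dims[2])
    theta <- atan2(-(rr - cs$center[1]), cc - cs$center[2]) * 180 / pi
    lab <- matrix(0L, dims[1], dims[2])
    lab[myo] <- base + sector_of_angle(theta[myo], cs$reference_angle,
                                       n_sectors)
    labels[, , s] <- lab
  }
  structure(list(labels = labels,
                 territories = data.frame(segment = 1:16,
                                          territory = segment_territories())),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  counts <- table(factor(x$labels[x$labels > 0], levels = 1:16))
  cat("<segment_map>", sum(counts), "myocardial pixels;",
      "segments present:", paste(which(counts > 0), collapse = " "), "\n")
  invisible(x)
}

#' Write/read contours as JSON
#'
#' Vertices are stored per slice under keys `"endo"` and `"epi"` as lists
#' of `[row, col]` pairs (1-based pixel coordinates).
#'
#' @param contours a `contour_set`.
#' @param path JSON path.
#' @return Invisibly, `path` (write) or the `contour_set` (read).
#' @name contour_io
#' @export
write_contours <- function(contours, path) {
  out <- lapply(contours, function(cs) list(
    endo = unname(apply(cs$endo, 1, function(v) c(v[1], v[2]),
                        simplify = FALSE)),
    epi = unname(apply(cs$epi, 1, function(v) c(v[1], v[2]),
                       simplify = FALSE)),
    center = cs$center, reference_angle = cs$reference_angle,
    source = if (is.null(cs$source)) "manual" else cs$source))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname contour_io
#' @export
read_contours <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(lapply(raw, function(cs) {
    if (is.null(cs$endo) || is.null(cs$epi))
      stop("malformed contour file ", path,
           ": slices need 'endo' and 'epi' vertex lists")
    list(endo = matrix(unlist(cs$endo), ncol = 2, byrow = TRUE,
                       dimnames = list(NULL, c("row", "col"))),
         epi = matrix(unlist(cs$epi), ncol = 2, byrow = TRUE,
                      dimnames = list(NULL, c("row", "col"))),
         center = as.numeric(cs$center),
         reference_angle = cs$reference_angle, source = cs$source)
  }), class = "contour_set")
}
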