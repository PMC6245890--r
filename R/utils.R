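#' fermiperf: quantitative first-pass myocardial perfusion analysis
#'
#' Motion correction, temporal-MIP contour delineation, dual-bolus AIF
#' construction, pixel-wise Fermi-constrained deconvolution and MPR-based
#' ischemia calling for dynamic stress/rest perfusion MRI, plus a synthetic
#' phantom generator and diagnostic-accuracy statistics.
#'
#' @keywords internal
"_PACKAGE"

# Rounding to 1 decimal, half away from zero (the reporting convention used
# throughout for percentages).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Bilinear sampling of a matrix at (possibly fractional) row/col positions.
# Coordinates outside the image are clamped to the edge value.
bilinear_sample <- function(img, rows, cols) {
  nr <- nrow(img)
  nc <- ncol(img)
  rows <- pmin(pmax(rows, 1), nr)
  cols <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(rows), nr - 1L)
  c0 <- pmin(floor(cols), nc - 1L)
  fr <- rows - r0
  fc <- cols - c0
  v00 <- img[cbind(r0, c0)]
  v10 <- img[cbind(r0 + 1, c0)]
  v01 <- img[cbind(r0, c0 + 1)]
  v11 <- img[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

# Even-odd ray-casting point-in-polygon test, vectorised over query points.
# poly: n x 2 matrix of (row, col) vertices, implicitly closed.
point_in_polygon <- function(rows, cols, poly) {
  n <- nrow(poly)
  inside <- logical(length(rows))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    crosses <- ((yi > rows) != (yj > rows)) &
      (cols < (xj - xi) * (rows - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Periodic (circular) moving average with an odd window length.
periodic_smooth <- function(x, window) {
  n <- length(x)
  window <- min(window, n - (1 - n %% 2))
  if (window < 2) return(x)
  half <- floor(window / 2)
  xx <- c(x[(n - half + 1):n], x, x[1:half])
  as.numeric(stats::filter(xx, rep(1 / (2 * half + 1), 2 * half + 1)))[
    (half + 1):(half + n)]
}
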