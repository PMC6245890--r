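#' Sampled time curve
#'
#' Lightweight container pairing sample times (seconds) with signal values,
#' used for arterial input functions and tissue enhancement curves.
#'
#' @param times numeric vector of strictly increasing sample times (s).
#' @param values numeric vector of the same length.
#' @return An object of class `sampled_curve` (a list with `times`, `values`).
#' @export
sampled_curve <- function(times, values) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("non-finite values in curve")
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "sampled_curve")
}

#' @export
print.sampled_curve <- function(x, ...) {
  cat(sprintf("<sampled_curve> %d samples, t = [%g, %g] s, peak %.4g\n",
              length(x$times), min(x$times), max(x$times), max(x$values)))
  invisible(x)
}

is_uniform <- function(times, tol = 1e-6) {
  if (length(times) < 3) return(TRUE)
  d <- diff(times)
  max(abs(d - d[1])) <= tol * abs(d[1])
}

#' Gamma-variate arterial input function parameters
#'
#' Parameters of the normalised gamma-variate bolus model used to simulate
#' the contrast concentration curve in the left-ventricular blood pool.
#' The curve peaks at `onset + alpha * beta` with peak value
#' `baseline + amplitude`; an optional recirculation term adds a delayed,
#' scaled copy of the first pass.
#'
#' @param amplitude peak enhancement above baseline (signal units).
#' @param onset bolus arrival time t_a (s).
#' @param alpha dimensionless shape parameter (> 0).
#' @param beta scale parameter (s, > 0).
#' @param recirculation_fraction fraction in `[0, 1)` of the first-pass
#'   amplitude re-appearing after `recirculation_delay`.
#' @param recirculation_delay delay of the recirculation bump (s).
#' @param baseline pre-contrast signal level.
#' @return An object of class `aif_params`.
#' @export
aif_params <- function(amplitude = 100, onset = 8, alpha = 3, beta = 2.5,
                       recirculation_fraction = 0, recirculation_delay = 20,
                       baseline = 0) {
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be positive")
  if (!is.finite(beta) || beta <= 0) stop("'beta' must be positive")
  if (recirculation_fraction < 0 || recirculation_fraction >= 1)
    stop("'recirculation_fraction' must be in [0, 1)")
  p <- list(amplitude = amplitude, onset = onset, alpha = alpha, beta = beta,
            recirculation_fraction = recirculation_fraction,
            recirculation_delay = recirculation_delay, baseline = baseline)
  if (any(!vapply(p, is.finite, logical(1)))) stop("parameters must be finite")
  structure(p, class = "aif_params")
}

# Normalised gamma-variate: 0 for t <= t_a, peak value 1 at t = t_a + alpha*beta.
gamma_variate <- function(t, onset, alpha, beta) {
  u <- (t - onset) / (alpha * beta)
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- u[pos]^alpha * exp(alpha * (1 - u[pos]))
  out
}

#' Evaluate a gamma-variate arterial input function
#'
#' @param params an [aif_params()] object.
#' @param times strictly increasing sample times (s).
#' @return A [sampled_curve()] with the AIF values (baseline included).
#' @examples
#' a <- make_aif(aif_params(amplitude = 1, onset = 5, alpha = 3, beta = 2),
#'               seq(0, 40, by = 0.5))
#' @export
make_aif <- function(params, times) {
  stopifnot(inherits(params, "aif_params"))
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  v <- params$amplitude * gamma_variate(times, params$onset,
                                        params$alpha, params$beta)
  if (params$recirculation_fraction > 0) {
    v <- v + params$recirculation_fraction * params$amplitude *
      gamma_variate(times, params$onset + params$recirculation_delay,
                    params$alpha, params$beta)
  }
  sampled_curve(times, params$baseline + v)
}

#' Fermi impulse-response parameters
#'
#' Parameters of the Fermi (logistic-decay) tissue impulse response
#' `h(t) = F / (1 + exp(k * (t - tau0)))` for `t >= 0` (0 for `t < 0`),
#' with a separate bolus arrival delay `td`. Myocardial blood flow is read
#' out as `h(0) = F / (1 + exp(-k * tau0))`.
#'
#' @param F flow amplitude (inverse time units of the sampling axis, >= 0).
#' @param k decay rate (1/s, in `[0, Inf)`).
#' @param tau0 shoulder width (s, >= 0).
#' @param td arrival delay (s, >= 0).
#' @return An object of class `fermi_params`.
#' @export
fermi_params <- function(F, k, tau0, td = 0) {
  vals <- c(F = F, k = k, tau0 = tau0, td = td)
  if (any(!is.finite(vals))) stop("Fermi parameters must be finite")
  if (any(vals < 0)) stop("Fermi parameters must be non-negative")
  structure(as.list(vals), class = "fermi_params")
}

#' Evaluate the Fermi impulse response
#'
#' @param params a [fermi_params()] object.
#' @param t times (s); values for `t < 0` are 0.
#' @return Numeric vector `h(t)`.
#' @export
fermi_ir <- function(params, t) {
  stopifnot(inherits(params, "fermi_params"))
  h <- params$F / (1 + exp(params$k * (t - params$tau0)))
  h[t < 0] <- 0
  h
}

#' Flow read-out of a Fermi impulse response
#'
#' `h(0) = F / (1 + exp(-k * tau0))`, the conventional myocardial blood flow
#' estimate of Fermi-constrained deconvolution.
#'
#' @param params a [fermi_params()] object (or list with `F`, `k`, `tau0`).
#' @return `h(0)`.
#' @export
fermi_mbf <- function(params) {
  params$F / (1 + exp(-params$k * params$tau0))
}

#' Synthesize a tissue enhancement curve from an AIF and a Fermi response
#'
#' Discrete convolution of the (delay-shifted) arterial input with the Fermi
#' impulse response on a uniform time grid:
#' `C_t[i] = dt * sum_{j <= i} C_a(t_j - td) * h((i - j) * dt)`.
#' A baseline-free input yields a baseline-free output.
#'
#' @param aif a [sampled_curve()], uniformly sampled.
#' @param params a [fermi_params()] object.
#' @return A [sampled_curve()] with the tissue curve on the same grid.
#' @export
make_tissue_curve <- function(aif, params) {
  stopifnot(inherits(aif, "sampled_curve"), inherits(params, "fermi_params"))
  times <- aif$times
  if (!is_uniform(times))
    stop("AIF must be uniformly sampled; resample before convolution")
  n <- length(times)
  dt <- if (n > 1) times[2] - times[1] else 1
  ca <- if (params$td > 0) {
    stats::approx(times, aif$values, xout = times - params$td,
                  yleft = 0, rule = 2)$y
  } else aif$values
  h <- fermi_ir(params, (seq_len(n) - 1) * dt)
  ct <- dt * discrete_causal_conv(ca, h)
  sampled_curve(times, ct)
}

# Causal discrete convolution (FFT-based): out[i] = sum_{j=1..i} x[j] * h[i-j+1].
discrete_causal_conv <- function(x, h) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  m <- stats::nextn(2 * n)
  xf <- stats::fft(c(x, numeric(m - n)))
  hf <- stats::fft(c(h, numeric(m - n)))
  Re(stats::fft(xf * hf, inverse = TRUE))[seq_len(n)] / m
}
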