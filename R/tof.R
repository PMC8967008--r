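#' Wiener deconvolution of a measured trace against a reference
#'
#' Frequency-domain division stabilised by a noise-floor regulariser:
#' `H = S * Conj(R) / (|R|^2 + reg * max|R|^2)`, inverse-transformed to a
#' real impulse-response trace.  A measured trace consisting of delayed,
#' scaled copies of the reference collapses to localised peaks at the
#' delays.  The lag axis runs from zero to the full window length (all
#' reflection delays are nonnegative).
#'
#' @param measured,reference [thz_waveform()] pair with identical sampling.
#' @param reg Regularisation parameter relative to the peak reference
#'   power (> 0); default 1e-4.
#' @return List with `lag` (ps, ascending through 0) and `response`.
#' @export
deconvolve <- function(measured, reference, reg = 1e-4) {
  stopifnot(inherits(measured, "thz_waveform"), inherits(reference, "thz_waveform"))
  if (length(measured$time) != length(reference$time) ||
      abs(measured$dt - reference$dt) > 1e-12) {
    stop("measured and reference must share the sampling grid", call. = FALSE)
  }
  if (!is.numeric(reg) || reg <= 0) stop("`reg` must be positive", call. = FALSE)
  n <- length(measured$field)
  rf <- stats::fft(reference$field)
  sf <- stats::fft(measured$field)
  p <- Mod(rf)^2
  h <- sf * Conj(rf) / (p + reg * max(p))
  imp <- Re(stats::fft(h, inverse = TRUE)) / n
  # reflection delays are nonnegative, so the lag axis runs 0..(n-1) dt
  # (a negative lag would alias to the far end of the window)
  lag <- (seq_len(n) - 1L) * measured$dt +
    (measured$time[1] - reference$time[1])
  list(lag = lag, response = imp)
}

#' Detect pulse arrival times in an impulse-response trace
#'
#' Finds the `n_expected` largest local extrema of the absolute response,
#' greedily enforcing a minimum separation, and refines each arrival to
#' sub-sample precision with a three-point parabola through the absolute
#' response.
#'
#' @param impulse List with `lag` and `response` (from [deconvolve()]).
#' @param n_expected Number of pulses: 2 (empty ERS) or 4 (with sample).
#' @param min_separation Minimum time between accepted peaks, ps.
#' @return Numeric vector of arrival times, ps, sorted ascending.
#' @export
detect_peaks <- function(impulse, n_expected = 4L, min_separation = 2) {
  if (!n_expected %in% c(2L, 4L)) {
    stop("`n_expected` must be 2 or 4", call. = FALSE)
  }
  a <- abs(impulse$response)
  lag <- impulse$lag
  n <- length(a)
  loc <- which(a[2:(n - 1L)] >= a[1:(n - 2L)] & a[2:(n - 1L)] >= a[3:n]) + 1L
  loc <- loc[order(a[loc], decreasing = TRUE)]
  picked <- integer(0)
  for (i in loc) {
    if (all(abs(lag[i] - lag[picked]) >= min_separation)) {
      picked <- c(picked, i)
      if (length(picked) == n_expected) break
    }
  }
  if (length(picked) < n_expected) {
    stop(sprintf("found only %d peak(s) separated by >= %g ps, expected %d",
                 length(picked), min_separation, n_expected), call. = FALSE)
  }
  dt <- lag[2] - lag[1]
  times <- vapply(picked, function(i) {
    y1 <- a[i - 1L]; y2 <- a[i]; y3 <- a[i + 1L]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (y1 - y3) / denom
    lag[i] + delta * dt
  }, 1)
  sort(times)
}

#' ERS arrival-time set
#'
#' Pulse arrival times from the empty and loaded external reference
#' structure, with optional per-interval timing standard deviations for
#' uncertainty propagation.
#'
#' @param t1o,t4o Empty-structure arrivals (beamsplitter, mirror), ps.
#' @param t1,t2,t3,t4 Loaded-structure arrivals (beamsplitter, sample
#'   front, sample back, mirror), ps.
#' @param sigma_t Named numeric vector of timing standard deviations, ps:
#'   names among `t14o`, `t12`, `t23`, `t34` (defaults 0).
#' @return An object of class `ers_timings`.
#' @export
ers_timings <- function(t1o, t4o, t1, t2, t3, t4,
                        sigma_t = c(t14o = 0, t12 = 0, t23 = 0, t34 = 0)) {
  if (!(t1o < t4o)) stop("need t1o < t4o", call. = FALSE)
  if (!(t1 < t2 && t2 < t3 && t3 < t4)) {
    stop("need t1 < t2 < t3 < t4", call. = FALSE)
  }
  full <- c(t14o = 0, t12 = 0, t23 = 0, t34 = 0)
  full[names(sigma_t)] <- sigma_t
  if (any(full < 0)) stop("timing sigmas must be nonnegative", call. = FALSE)
  structure(list(t1o = t1o, t4o = t4o, t1 = t1, t2 = t2, t3 = t3, t4 = t4,
                 sigma_t = full),
            class = "ers_timings")
}

#' Beamsplitter-to-mirror distance of the empty ERS
#'
#' `L14 = c0 (t4o - t1o) / 2`; the factor 2 accounts for the double pass of
#' the mirror reflection.
#'
#' @param t1o,t4o Empty-structure arrival times, ps (`t4o > t1o`).
#' @return Distance, mm.
#' @export
ers_empty_distance <- function(t1o, t4o) {
  if (!(t4o > t1o)) stop("need t4o > t1o", call. = FALSE)
  thz_c0 * (t4o - t1o) / 2
}

#' Sample thickness from ERS time-of-flight
#'
#' `L = (c0/2) [(t4o - t1o) - (t2 - t1) - (t4 - t3)]`: the air gaps on
#' either side of the sample are subtracted from the empty-structure path,
#' leaving the geometric thickness independent of the sample's refractive
#' index.
#'
#' @param t An [ers_timings()].
#' @return Thickness, mm.
#' @export
ers_thickness <- function(t) {
  stopifnot(inherits(t, "ers_timings"))
  L <- thz_c0 / 2 * ((t$t4o - t$t1o) - (t$t2 - t$t1) - (t$t4 - t$t3))
  if (L <= 0) stop("inconsistent ERS geometry: nonpositive thickness", call. = FALSE)
  L
}

#' Refractive index from ERS time-of-flight
#'
#' `n_r = c0 (t3 - t2) / (2 L)`: the optical path through the sample versus
#' its geometric thickness.  The value is representative of the spectral
#' peak of the pulse (nominally ~0.2 THz for this class of source).
#'
#' @param t An [ers_timings()].
#' @param L Sample thickness, mm (> 0), typically from [ers_thickness()].
#' @return Refractive index (warns when below 1, which is physically
#'   unusual for amber).
#' @export
ers_refractive_index <- function(t, L) {
  stopifnot(inherits(t, "ers_timings"))
  if (L <= 0) stop("`L` must be positive (mm)", call. = FALSE)
  nr <- thz_c0 * (t$t3 - t$t2) / (2 * L)
  if (nr < 1) warning("recovered index below 1 (physically unusual)")
  nr
}

#' Propagated uncertainty of the ERS refractive index
#'
#' First-order propagation of the timing uncertainties through the
#' thickness and index formulas:
#' `(sigma_n/n)^2 = (sigma_t23/t23)^2 +
#'  (sigma_t14o^2 + sigma_t12^2 + sigma_t34^2) / (t14o - t12 - t34)^2`
#' with `t_mn = t_m - t_n`.
#'
#' @param t An [ers_timings()] with `sigma_t` filled in.
#' @return List with `relative` (sigma_n / n) and `absolute` (sigma_n,
#'   using the index implied by the timings).
#' @export
index_uncertainty <- function(t) {
  stopifnot(inherits(t, "ers_timings"))
  t23 <- t$t3 - t$t2
  denom <- (t$t4o - t$t1o) - (t$t2 - t$t1) - (t$t4 - t$t3)
  if (denom == 0) stop("degenerate geometry: zero net thickness path", call. = FALSE)
  s <- t$sigma_t
  rel2 <- (s[["t23"]] / t23)^2 +
    (s[["t14o"]]^2 + s[["t12"]]^2 + s[["t34"]]^2) / denom^2
  rel <- sqrt(rel2)
  n <- t23 / denom   # = c0 t23 / (2 L)
  list(relative = rel, absolute = rel * n)
}

#' Measure ERS timings from waveforms
#'
#' Convenience pipeline: deconvolve the empty and loaded ERS traces against
#' the reference, detect two and four arrivals respectively, and assemble
#' an [ers_timings()].
#'
#' @param empty,loaded,reference [thz_waveform()] traces (empty structure,
#'   structure with sample, bare reference pulse).
#' @param reg Deconvolution regulariser.
#' @param min_separation Minimum peak separation, ps.
#' @param sigma_t Passed through to [ers_timings()].
#' @return An [ers_timings()].
#' @export
measure_ers <- function(empty, loaded, reference, reg = 1e-4,
                        min_separation = 2,
                        sigma_t = c(t14o = 0, t12 = 0, t23 = 0, t34 = 0)) {
  te <- detect_peaks(deconvolve(empty, reference, reg), n_expected = 2L,
                     min_separation = min_separation)
  tl <- detect_peaks(deconvolve(loaded, reference, reg), n_expected = 4L,
                     min_separation = min_separation)
  ers_timings(te[1], te[2], tl[1], tl[2], tl[3], tl[4], sigma_t = sigma_t)
}
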