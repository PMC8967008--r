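#' Time-domain terahertz waveform
#'
#' Container for a uniformly sampled electric-field trace.  The time axis is
#' in picoseconds with constant spacing; the field is in arbitrary units.
#'
#' @param time Numeric vector of sample times, ps.  Must be strictly
#'   increasing with uniform spacing (relative jitter below 1e-9).
#' @param field Numeric vector of field amplitudes, same length as `time`,
#'   all finite.  At least 16 samples are required.
#' @param role One of `"reference"`, `"sample"`, `"ers_empty"`,
#'   `"ers_sample"`.
#' @param n_averages Number of averaged acquisitions this trace represents.
#'
#' @return An object of class `thz_waveform`: a list with elements `time`,
#'   `field`, `role`, `n_averages` and `dt` (the sample spacing, ps).
#' @export
thz_waveform <- function(time, field,
                         role = c("reference", "sample", "ers_empty", "ers_sample"),
                         n_averages = 1L) {
  role <- match.arg(role)
  if (!is.numeric(time) || !is.numeric(field)) {
    stop("`time` and `field` must be numeric vectors", call. = FALSE)
  }
  if (length(time) != length(field)) {
    stop("`time` and `field` must have equal length", call. = FALSE)
  }
  if (length(time) < 16L) {
    stop("waveform must have at least 16 samples", call. = FALSE)
  }
  if (!all(is.finite(time)) || !all(is.finite(field))) {
    stop("waveform values must be finite", call. = FALSE)
  }
  dt <- diff(time)
  if (any(dt <= 0)) {
    stop("time axis must be strictly increasing", call. = FALSE)
  }
  if ((max(dt) - min(dt)) / mean(dt) > 1e-9) {
    stop("time axis must be uniformly spaced (relative jitter < 1e-9)",
         call. = FALSE)
  }
  structure(
    list(time = as.numeric(time), field = as.numeric(field),
         role = role, n_averages = as.integer(n_averages),
         dt = mean(dt)),
    class = "thz_waveform"
  )
}

#' @export
print.thz_waveform <- function(x, ...) {
  cat(sprintf("<thz_waveform> role=%s  n=%d  dt=%.4g ps  window=%.4g ps  averages=%d\n",
              x$role, length(x$time), x$dt,
              x$time[length(x$time)] - x$time[1] + x$dt, x$n_averages))
  invisible(x)
}

#' Read a waveform file
#'
#' Waveform files are two-column delimited text (time in ps, field in
#' arbitrary units), whitespace- or comma-separated, with optional `#`
#' comment headers.  Recognised header keys: `# role=<role>` and
#' `# averages=<n>`.
#'
#' @param path Path to the file.
#' @param role Optional role overriding any header value.
#' @return A [thz_waveform()].
#' @export
load_waveform <- function(path, role = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  header <- grep("^\\s*#", lines, value = TRUE)
  hdr_role <- sub(".*role=([a-z_]+).*", "\\1",
                  grep("role=", header, value = TRUE)[1])
  hdr_avg <- suppressWarnings(as.integer(
    sub(".*averages=([0-9]+).*", "\\1",
        grep("averages=", header, value = TRUE)[1])))
  body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(body_idx) == 0L) stop("no data rows in ", path, call. = FALSE)
  fields <- strsplit(trimws(lines[body_idx]), "[,[:space:]]+")
  bad <- which(vapply(fields, length, 1L) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed waveform file %s: expected 2 columns at line %d",
                 path, body_idx[bad[1]]), call. = FALSE)
  }
  vals <- suppressWarnings(vapply(fields, function(f) as.numeric(f), numeric(2)))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2, any))[1]
    stop(sprintf("malformed waveform file %s: non-numeric value at line %d",
                 path, body_idx[bad]), call. = FALSE)
  }
  if (is.null(role)) {
    role <- if (!is.na(hdr_role) && hdr_role %in%
                c("reference", "sample", "ers_empty", "ers_sample")) {
      hdr_role
    } else "reference"
  }
  thz_waveform(vals[1, ], vals[2, ], role = role,
               n_averages = if (is.na(hdr_avg)) 1L else hdr_avg)
}

#' Write a waveform file
#'
#' Inverse of [load_waveform()]: two-column text with `#` headers carrying
#' the role and average count.
#'
#' @param w A [thz_waveform()].
#' @param path Output path.
#' @param digits Significant digits for the numeric columns.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(w, path, digits = 17L) {
  stopifnot(inherits(w, "thz_waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# role=%s", w$role),
               sprintf("# averages=%d", w$n_averages),
               "# columns=time_ps,field"), con)
  writeLines(sprintf("%.*g,%.*g", digits, w$time, digits, w$field), con)
  invisible(path)
}

#' Complex spectrum of a waveform
#'
#' Discrete Fourier transform of the (optionally zero-padded and tapered)
#' trace.  Only nonnegative frequencies are retained; the frequency
#' resolution is `1/(N * dt * zero_pad_factor)` THz.
#'
#' @param w A [thz_waveform()].
#' @param zero_pad_factor Integer >= 1; the trace is zero-padded to
#'   `zero_pad_factor` times its length before transforming.
#' @param window Taper applied before transforming: `"none"` (rectangular,
#'   the default) or `"hann"`.
#' @return An object of class `thz_spectrum`: list with `frequency` (THz,
#'   ascending from 0), complex `amplitude`, and bookkeeping fields `dt`,
#'   `n_time` (padded length) and `role`.
#' @export
compute_spectrum <- function(w, zero_pad_factor = 1L, window = c("none", "hann")) {
  stopifnot(inherits(w, "thz_waveform"))
  window <- match.arg(window)
  if (!is.numeric(zero_pad_factor) || zero_pad_factor < 1 ||
      zero_pad_factor != round(zero_pad_factor)) {
    stop("`zero_pad_factor` must be an integer >= 1", call. = FALSE)
  }
  x <- w$field
  n0 <- length(x)
  if (window == "hann") {
    x <- x * (0.5 - 0.5 * cos(2 * pi * seq_len(n0) / (n0 + 1)))
  }
  n <- n0 * as.integer(zero_pad_factor)
  if (n > n0) x <- c(x, numeric(n - n0))
  amp <- stats::fft(x)
  keep <- seq_len(n %/% 2 + 1L)
  freq <- (keep - 1L) / (n * w$dt)
  structure(
    list(frequency = freq, amplitude = amp[keep],
         dt = w$dt, n_time = n, role = w$role),
    class = "thz_spectrum"
  )
}

#' @export
print.thz_spectrum <- function(x, ...) {
  cat(sprintf("<thz_spectrum> role=%s  %d bins  df=%.5g THz  fmax=%.4g THz\n",
              x$role, length(x$frequency),
              x$frequency[2] - x$frequency[1],
              max(x$frequency)))
  invisible(x)
}

#' Reconstruct a time-domain waveform from its one-sided spectrum
#'
#' Inverts [compute_spectrum()] for an untapered, unpadded spectrum by
#' restoring Hermitian symmetry and applying the inverse DFT.
#'
#' @param s A `thz_spectrum` from [compute_spectrum()] with `window = "none"`
#'   and `zero_pad_factor = 1`.
#' @param t0 Time of the first sample, ps.
#' @return A [thz_waveform()].
#' @export
waveform_from_spectrum <- function(s, t0 = 0) {
  stopifnot(inherits(s, "thz_spectrum"))
  n <- s$n_time
  k <- length(s$amplitude)
  # restore the negative-frequency half by Hermitian symmetry
  full <- c(s$amplitude, Conj(rev(s$amplitude[2:(k - (1L - n %% 2L))])))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  thz_waveform(t0 + (seq_len(n) - 1L) * s$dt, x, role = s$role)
}

#' Usable frequency band of a spectrum pair
#'
#' The usable band of a THz-TDS measurement is limited at low frequency by
#' vanishing source power and at high frequency by the noise floor.  This
#' returns the widest contiguous band in which both the reference and the
#' sample magnitude exceed the estimated noise floor by `dynamic_range_db`
#' decibels.  The noise floor is estimated as the median reference magnitude
#' above 3 THz (beyond the source band, so spectral content there is noise);
#' the lower band edge is never placed below `f_min_floor` (default 0.1 THz,
#' below which the source emits very little power).
#'
#' @param sample,reference `thz_spectrum` objects on identical frequency
#'   grids.
#' @param dynamic_range_db Required margin above the noise floor, dB
#'   (field-amplitude dB, i.e. 20 log10).
#' @param f_min_floor Hard lower limit for the band edge, THz.
#' @return A [band_mask()].
#' @export
usable_band <- function(sample, reference, dynamic_range_db = 20,
                        f_min_floor = 0.1) {
  stopifnot(inherits(sample, "thz_spectrum"), inherits(reference, "thz_spectrum"))
  if (length(sample$frequency) != length(reference$frequency) ||
      max(abs(sample$frequency - reference$frequency)) > 1e-12) {
    stop("spectra must share a frequency grid", call. = FALSE)
  }
  f <- reference$frequency
  mag_r <- Mod(reference$amplitude)
  mag_s <- Mod(sample$amplitude)
  hi <- f > 3
  floor_est <- if (any(hi)) stats::median(mag_r[hi]) else 0
  thresh <- max(floor_est, .Machine$double.xmin) * 10^(dynamic_range_db / 20)
  ok <- mag_r > thresh & mag_s > thresh & f >= f_min_floor
  if (!any(ok)) stop("no frequency satisfies the dynamic-range criterion",
                     call. = FALSE)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  true_runs <- which(runs$values)
  widest <- true_runs[which.max(runs$lengths[true_runs])]
  band_mask(f[starts[widest]], f[ends[widest]])
}

#' Frequency band mask
#'
#' @param f_low,f_high Band edges in THz, `0 <= f_low < f_high`.
#' @return An object of class `band_mask`.
#' @export
band_mask <- function(f_low, f_high) {
  if (!is.finite(f_low) || !is.finite(f_high) || f_low < 0 || f_low >= f_high) {
    stop("band mask requires 0 <= f_low < f_high", call. = FALSE)
  }
  structure(list(f_low = f_low, f_high = f_high), class = "band_mask")
}

#' @export
print.band_mask <- function(x, ...) {
  cat(sprintf("<band_mask> [%.4g, %.4g] THz\n", x$f_low, x$f_high))
  invisible(x)
}

in_band <- function(frequency, band) {
  frequency >= band$f_low & frequency <= band$f_high
}

#' Centered moving-average smoothing
#'
#' Centered moving average with an odd window; at the edges the window
#' shrinks symmetrically so the output has the same length as the input.
#' Used to suppress Fabry-Perot interference fringes in extracted
#' permittivity spectra.
#'
#' @param values Numeric series (on a uniform frequency grid).
#' @param window_points Odd positive integer, at most `length(values)`.
#' @return Smoothed series, same length.
#' @export
moving_average_smooth <- function(values, window_points = 11L) {
  n <- length(values)
  w <- window_points
  if (!is.numeric(w) || length(w) != 1L || w < 1 || w != round(w) ||
      w %% 2 == 0) {
    stop("`window_points` must be an odd positive integer", call. = FALSE)
  }
  if (w > n) stop("`window_points` exceeds series length", call. = FALSE)
  if (w == 1L) return(values)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, values))
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[i] <- (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
  }
  out
}
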