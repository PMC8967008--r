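#' Permittivity spectrum
#'
#' Complex relative permittivity eps = eps_r - i eps_i tabulated against
#' frequency over a usable band.
#'
#' @param frequency Frequencies, THz, ascending.
#' @param eps_r,eps_i Real and imaginary (loss) parts.
#' @param band [band_mask()] of the usable range.
#' @param smooth_window Moving-average window used to produce the spectrum
#'   (provenance; 1 = unsmoothed).
#' @return An object of class `permittivity_spectrum`.
#' @export
permittivity_spectrum <- function(frequency, eps_r, eps_i, band,
                                  smooth_window = 1L) {
  stopifnot(inherits(band, "band_mask"),
            length(frequency) == length(eps_r),
            length(frequency) == length(eps_i))
  if (is.unsorted(frequency, strictly = TRUE)) {
    stop("`frequency` must be strictly ascending", call. = FALSE)
  }
  structure(list(frequency = frequency, eps_r = eps_r, eps_i = eps_i,
                 band = band, smooth_window = as.integer(smooth_window)),
            class = "permittivity_spectrum")
}

#' @export
print.permittivity_spectrum <- function(x, ...) {
  sel <- in_band(x$frequency, x$band)
  cat(sprintf("<permittivity_spectrum> %d points, band [%.3g, %.3g] THz, smooth=%d\n",
              length(x$frequency), x$band$f_low, x$band$f_high, x$smooth_window))
  if (any(sel)) {
    cat(sprintf("  in-band eps_r: %.4g..%.4g   eps_i: %.4g..%.4g\n",
                min(x$eps_r[sel]), max(x$eps_r[sel]),
                min(x$eps_i[sel]), max(x$eps_i[sel])))
  }
  invisible(x)
}

#' Read/write permittivity CSV
#'
#' Three-column CSV `freq_THz,eps_real,eps_imag`, optional `#` comment
#' header lines (used for provenance).  This layout matches common
#' spreadsheet exports of permittivity tables.
#'
#' @param path File path.
#' @param band Optional [band_mask()]; default spans the file's frequency
#'   range.
#' @return [load_permittivity()]: a [permittivity_spectrum()].
#' @export
load_permittivity <- function(path, band = NULL) {
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("freq_THz", "eps_real", "eps_imag")
  if (!all(need %in% names(d))) {
    stop("permittivity file must have columns freq_THz,eps_real,eps_imag",
         call. = FALSE)
  }
  d <- d[order(d$freq_THz), ]
  if (is.null(band)) band <- band_mask(min(d$freq_THz), max(d$freq_THz))
  permittivity_spectrum(d$freq_THz, d$eps_real, d$eps_imag, band)
}

#' @rdname load_permittivity
#' @param perm A [permittivity_spectrum()].
#' @param comments Character vector of extra provenance comment lines.
#' @export
write_permittivity <- function(perm, path, comments = character()) {
  stopifnot(inherits(perm, "permittivity_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# band_THz=%.6g,%.6g", perm$band$f_low, perm$band$f_high),
               sprintf("# smooth_window=%d", perm$smooth_window),
               paste0("# ", comments)[length(comments) > 0]), con)
  writeLines("freq_THz,eps_real,eps_imag", con)
  writeLines(sprintf("%.10g,%.10g,%.10g", perm$frequency, perm$eps_r,
                     perm$eps_i), con)
  invisible(path)
}

#' Unwrapped phase difference between reference and sample spectra
#'
#' Computes the per-frequency phase of E_R/E_S, unwraps it along ascending
#' frequency within the band, and anchors the absolute 2*pi*k branch by
#' requiring a linear fit over the lowest quartile of the band to
#' extrapolate as close as possible to zero phase at zero frequency (a
#' transparent slab imposes a phase delay proportional to frequency).
#'
#' @param sample,reference `thz_spectrum` objects on a common grid.
#' @param band A [band_mask()].
#' @return List with `frequency` (in-band, THz) and `delta_phi` (radians).
#' @export
phase_difference <- function(sample, reference, band) {
  stopifnot(inherits(sample, "thz_spectrum"), inherits(reference, "thz_spectrum"),
            inherits(band, "band_mask"))
  if (length(sample$frequency) != length(reference$frequency) ||
      max(abs(sample$frequency - reference$frequency)) > 1e-12) {
    stop("spectra must share a frequency grid", call. = FALSE)
  }
  sel <- in_band(reference$frequency, band) & reference$frequency > 0
  if (sum(sel) < 5L) stop("band narrower than 5 grid points", call. = FALSE)
  f <- reference$frequency[sel]
  dphi <- signal::unwrap(Arg(reference$amplitude[sel] / sample$amplitude[sel]))
  # anchor the overall 2*pi*k offset at zero frequency
  nq <- max(5L, ceiling(length(f) / 4))
  co <- stats::coef(stats::lm(dphi[seq_len(nq)] ~ f[seq_len(nq)]))
  k <- round(co[[1]] / (2 * pi))
  list(frequency = f, delta_phi = dphi - 2 * pi * k)
}

#' Real refractive index from the phase difference
#'
#' `n_r(omega) = 1 + c0 * delta_phi / (omega * L)` with `omega = 2 pi f`.
#'
#' @param delta_phi Phase difference, radians (list from
#'   [phase_difference()] or a numeric vector).
#' @param frequency Frequencies, THz (ignored when `delta_phi` carries its
#'   own).
#' @param L Sample thickness, mm (> 0).
#' @return Numeric vector `n_r`.
#' @export
real_refractive_index <- function(delta_phi, L, frequency = NULL) {
  if (is.list(delta_phi)) {
    frequency <- delta_phi$frequency
    delta_phi <- delta_phi$delta_phi
  }
  if (L <= 0) stop("`L` must be positive (mm)", call. = FALSE)
  if (any(frequency <= 0)) stop("zero frequency must be excluded", call. = FALSE)
  1 + thz_c0 * delta_phi / (2 * pi * frequency * L)
}

#' Fresnel transmission coefficients at normal incidence
#'
#' Field transmission air -> sample (`t12 = 2/(1 + n_r)`) and sample -> air
#' (`t21 = 2 n_r/(n_r + 1)`), valid in the weak-absorption regime where the
#' real index dominates.
#'
#' @param n_r Real refractive index (> 0), vectorised.
#' @return List with `t12` and `t21`.
#' @export
fresnel_coefficients <- function(n_r) {
  if (any(n_r <= 0)) stop("`n_r` must be positive", call. = FALSE)
  list(t12 = 2 / (1 + n_r), t21 = 2 * n_r / (n_r + 1))
}

#' Imaginary refractive index with Fresnel correction
#'
#' `n_i(omega) = c0/(omega L) * ln(|E_R|/|E_S| * t12 * t21)`: the measured
#' amplitude ratio is corrected for the reflection loss at the two
#' interfaces before being attributed to absorption.  Small negative values
#' (possible through noise or fringe residue) are clipped to zero and
#' counted.
#'
#' @param sample,reference `thz_spectrum` objects on a common grid.
#' @param n_r Real index on the in-band grid (for the Fresnel factors).
#' @param L Thickness, mm.
#' @param band A [band_mask()].
#' @return List with `frequency`, `n_i`, and `n_clipped` (count of negative
#'   values clipped to 0).
#' @export
imaginary_refractive_index <- function(sample, reference, n_r, L, band) {
  stopifnot(inherits(sample, "thz_spectrum"), inherits(reference, "thz_spectrum"))
  if (L <= 0) stop("`L` must be positive (mm)", call. = FALSE)
  sel <- in_band(reference$frequency, band) & reference$frequency > 0
  f <- reference$frequency[sel]
  es <- Mod(sample$amplitude[sel])
  er <- Mod(reference$amplitude[sel])
  if (any(es == 0)) {
    stop(sprintf("zero sample amplitude at %.4g THz", f[which(es == 0)[1]]),
         call. = FALSE)
  }
  tr <- fresnel_coefficients(n_r)
  ni <- thz_c0 / (2 * pi * f * L) * log(er / es * tr$t12 * tr$t21)
  clipped <- sum(ni < 0)
  ni[ni < 0] <- 0
  list(frequency = f, n_i = ni, n_clipped = clipped)
}

#' Permittivity from the complex refractive index
#'
#' Under eps = eps_r - i eps_i and n = n_r - i n_i with n^2 = eps:
#' `eps_r = n_r^2 - n_i^2`, `eps_i = 2 n_r n_i` (nonnegative for absorbing
#' media).
#'
#' @param frequency Frequencies, THz.
#' @param n_r,n_i Real and imaginary index.
#' @param band A [band_mask()].
#' @param smooth_window Provenance tag, see [permittivity_spectrum()].
#' @return A [permittivity_spectrum()].
#' @export
permittivity_from_index <- function(frequency, n_r, n_i, band,
                                    smooth_window = 1L) {
  permittivity_spectrum(frequency, n_r^2 - n_i^2, 2 * n_r * n_i, band,
                        smooth_window = smooth_window)
}

#' Extract the complex permittivity from a waveform pair
#'
#' Composite pipeline: Fourier-transform both traces, select the usable
#' band, unwrap the phase difference, convert phase to real index and
#' Fresnel-corrected amplitude ratio to imaginary index, square up to the
#' permittivity, and smooth both parts with a centered moving average to
#' suppress Fabry-Perot fringes from the slab's parallel faces.
#'
#' @param sample,reference [thz_waveform()] pair with identical sampling.
#' @param L Sample thickness, mm.
#' @param band Optional [band_mask()] overriding the automatic
#'   [usable_band()].
#' @param smooth_window Odd moving-average length applied to eps_r and
#'   eps_i (1 disables; instrument practice is 10-15 points).
#' @param zero_pad_factor Passed to [compute_spectrum()].
#' @param dynamic_range_db Passed to [usable_band()] when `band` is `NULL`.
#' @param time_gate Optional time, ps: sample-field values after this time
#'   are zeroed before transforming, excluding Fabry-Perot echoes entirely
#'   (validation aid; the standard treatment is smoothing).
#' @return A [permittivity_spectrum()] with attribute `n_clipped` (count of
#'   negative n_i values clipped).
#' @export
extract_permittivity <- function(sample, reference, L, band = NULL,
                                 smooth_window = 11L, zero_pad_factor = 1L,
                                 dynamic_range_db = 20, time_gate = NULL) {
  stopifnot(inherits(sample, "thz_waveform"), inherits(reference, "thz_waveform"))
  if (length(sample$time) != length(reference$time) ||
      abs(sample$dt - reference$dt) > 1e-12) {
    stop("sample and reference must share the sampling grid", call. = FALSE)
  }
  if (!is.null(time_gate)) {
    fld <- sample$field
    fld[sample$time > time_gate] <- 0
    sample <- thz_waveform(sample$time, fld, role = sample$role,
                           n_averages = sample$n_averages)
  }
  ss <- compute_spectrum(sample, zero_pad_factor = zero_pad_factor)
  rs <- compute_spectrum(reference, zero_pad_factor = zero_pad_factor)
  if (is.null(band)) band <- usable_band(ss, rs, dynamic_range_db = dynamic_range_db)
  ph <- phase_difference(ss, rs, band)
  nr <- real_refractive_index(ph, L)
  im <- imaginary_refractive_index(ss, rs, nr, L, band)
  perm <- permittivity_from_index(ph$frequency, nr, im$n_i, band,
                                  smooth_window = smooth_window)
  if (smooth_window > 1L) {
    perm$eps_r <- moving_average_smooth(perm$eps_r, smooth_window)
    perm$eps_i <- moving_average_smooth(perm$eps_i, smooth_window)
  }
  attr(perm, "n_clipped") <- im$n_clipped
  perm
}
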