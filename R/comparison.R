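#' Reference library of permittivity spectra
#'
#' Named collection of [permittivity_spectrum()] records (e.g. one per
#' amber deposit) against which unknown samples are screened.
#'
#' @param entries Named list of [permittivity_spectrum()] objects (at least
#'   one; all names unique and non-empty).
#' @return An object of class `reference_library`.
#' @export
reference_library <- function(entries) {
  stopifnot(is.list(entries), length(entries) >= 1L)
  nm <- names(entries)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop("library entries must have unique non-empty names", call. = FALSE)
  }
  ok <- vapply(entries, inherits, TRUE, "permittivity_spectrum")
  if (!all(ok)) stop("all entries must be permittivity spectra", call. = FALSE)
  structure(list(entries = entries), class = "reference_library")
}

#' Distance between two permittivity spectra
#'
#' Both spectra are restricted to their common band (which must span at
#' least `min_overlap` THz) and the finer-gridded spectrum is linearly
#' interpolated onto the coarser grid (no extrapolation).  Reported
#' distances: mean absolute difference (MAD) of eps_r, MAD of eps_i, the
#' absolute difference of the loss-peak frequencies, and a combined score
#' `max(mad_eps_r, mad_eps_i)`.
#'
#' @param a,b [permittivity_spectrum()] objects.
#' @param min_overlap Minimum common-band width, THz.
#' @return List with `mad_eps_r`, `mad_eps_i`, `d_peak_freq`, `combined`,
#'   `band` (the common [band_mask()]).
#' @export
spectrum_distance <- function(a, b, min_overlap = 0.3) {
  stopifnot(inherits(a, "permittivity_spectrum"),
            inherits(b, "permittivity_spectrum"))
  lo <- max(a$band$f_low, b$band$f_low)
  hi <- min(a$band$f_high, b$band$f_high)
  if (!is.finite(lo) || hi - lo < min_overlap) {
    stop(sprintf("band overlap %.3g THz is below the required %.3g THz",
                 max(hi - lo, 0), min_overlap), call. = FALSE)
  }
  band <- band_mask(lo, hi)
  sa <- in_band(a$frequency, band)
  sb <- in_band(b$frequency, band)
  # interpolate onto the coarser in-band grid
  grid <- if (sum(sa) <= sum(sb)) a$frequency[sa] else b$frequency[sb]
  ar <- stats::approx(a$frequency, a$eps_r, xout = grid)$y
  ai <- stats::approx(a$frequency, a$eps_i, xout = grid)$y
  br <- stats::approx(b$frequency, b$eps_r, xout = grid)$y
  bi <- stats::approx(b$frequency, b$eps_i, xout = grid)$y
  pk <- function(f, y, s) f[s][which.max(y[s])]
  list(mad_eps_r = mean(abs(ar - br)),
       mad_eps_i = mean(abs(ai - bi)),
       d_peak_freq = abs(pk(a$frequency, a$eps_i, sa) -
                           pk(b$frequency, b$eps_i, sb)),
       combined = max(mean(abs(ar - br)), mean(abs(ai - bi))),
       band = band)
}

#' Screen a sample against a permittivity reference library
#'
#' Computes the [spectrum_distance()] from the query to every library
#' entry.  The verdict is `"outside library range"` when the minimum
#' combined score exceeds `flag_factor` times the library's median pairwise
#' combined score (its internal spread); with a single-entry library the
#' spread is undefined and a documented absolute threshold
#' (`abs_threshold`) is used instead.  This is a screening heuristic for
#' flagging grossly dissimilar materials (e.g. synthetic resin
#' counterfeits), not an authentication guarantee.
#'
#' @param query A [permittivity_spectrum()].
#' @param lib A [reference_library()].
#' @param flag_factor Multiplier on the library spread (default 2).
#' @param abs_threshold Fallback absolute combined-score threshold used
#'   when the library has a single entry (default 0.2).
#' @return List with `verdict` (`"inside library range"` /
#'   `"outside library range"`), `nearest` (entry name), `min_score`,
#'   `threshold`, `scores` (data frame per entry, distance columns plus
#'   `note` for skipped entries), `n_skipped`.
#' @export
screen_sample <- function(query, lib, flag_factor = 2, abs_threshold = 0.2) {
  stopifnot(inherits(query, "permittivity_spectrum"),
            inherits(lib, "reference_library"))
  nm <- names(lib$entries)
  rows <- lapply(nm, function(k) {
    d <- tryCatch(spectrum_distance(query, lib$entries[[k]]),
                  error = function(e) NULL)
    if (is.null(d)) {
      data.frame(entry = k, mad_eps_r = NA, mad_eps_i = NA,
                 d_peak_freq = NA, combined = NA,
                 note = "insufficient band overlap", stringsAsFactors = FALSE)
    } else {
      data.frame(entry = k, mad_eps_r = d$mad_eps_r, mad_eps_i = d$mad_eps_i,
                 d_peak_freq = d$d_peak_freq, combined = d$combined,
                 note = "", stringsAsFactors = FALSE)
    }
  })
  scores <- do.call(rbind, rows)
  usable <- scores[!is.na(scores$combined), ]
  if (nrow(usable) == 0L) {
    stop("no library entry shares enough band with the query", call. = FALSE)
  }
  usable <- usable[order(usable$combined), ]
  # library internal spread: median pairwise combined score
  k <- length(lib$entries)
  if (k >= 2L) {
    pw <- c()
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        d <- tryCatch(spectrum_distance(lib$entries[[i]], lib$entries[[j]]),
                      error = function(e) NULL)
        if (!is.null(d)) pw <- c(pw, d$combined)
      }
    }
    threshold <- if (length(pw)) flag_factor * stats::median(pw) else abs_threshold
  } else {
    threshold <- abs_threshold
  }
  min_score <- usable$combined[1]
  list(verdict = if (min_score > threshold) "outside library range"
       else "inside library range",
       nearest = usable$entry[1],
       min_score = min_score,
       threshold = threshold,
       scores = scores,
       n_skipped = sum(is.na(scores$combined)))
}
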