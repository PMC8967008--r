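#' Band-averaged field transmission of one pixel
#'
#' `T` is the unweighted mean over in-band frequencies of the field
#' magnitude ratio `|E_S(f)| / |E_R(f)|`; the image contrast quantity is
#' `ln(T)` (0 for a perfectly transparent pixel, negative where inclusions
#' scatter or absorb).
#'
#' @param sample,reference `thz_spectrum` objects on a common grid.
#' @param band A [band_mask()] (imaging default 1.5-2 THz).
#' @return List with `transmission` (T) and `ln_t`.
#' @export
pixel_transmission <- function(sample, reference, band = band_mask(1.5, 2)) {
  stopifnot(inherits(sample, "thz_spectrum"), inherits(reference, "thz_spectrum"))
  if (length(sample$frequency) != length(reference$frequency) ||
      max(abs(sample$frequency - reference$frequency)) > 1e-12) {
    stop("spectra must share a frequency grid", call. = FALSE)
  }
  sel <- in_band(reference$frequency, band)
  if (!any(sel)) stop("band contains no frequency samples", call. = FALSE)
  tt <- mean(Mod(sample$amplitude[sel]) / Mod(reference$amplitude[sel]))
  list(transmission = tt, ln_t = log(tt))
}

#' Raster transmission image
#'
#' @param x,y Pixel-center coordinates, mm.
#' @param values Matrix of ln(T) values (rows = y, columns = x).
#' @param band [band_mask()] used for the band average.
#' @param pixel_size Pixel size, mm.
#' @param n_waveform_averages Waveform averages per pixel.
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(x, y, values, band, pixel_size,
                         n_waveform_averages = 1L) {
  stopifnot(is.matrix(values), nrow(values) == length(y),
            ncol(values) == length(x), inherits(band, "band_mask"))
  structure(list(x = x, y = y, values = values, band = band,
                 pixel_size = pixel_size,
                 n_waveform_averages = as.integer(n_waveform_averages)),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d pixels at %.3g mm, band [%.3g, %.3g] THz, ln T in [%.3g, %.3g]\n",
              ncol(x$values), nrow(x$values), x$pixel_size,
              x$band$f_low, x$band$f_high,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Simulate a raster transmission scan over a material map
#'
#' For every pixel, the reference pulse is propagated through that pixel's
#' slab, `averages` noisy acquisitions are averaged (white amplitude noise
#' of standard deviation `noise_sigma`), and the band-averaged ln(T) is
#' computed against the clean reference.  Transfer functions are cached per
#' unique material, so maps with a few feature materials scan quickly.
#' Deterministic for a fixed seed.
#'
#' @param map A [make_material_map()].
#' @param reference A [thz_waveform()].
#' @param band A [band_mask()].
#' @param averages Waveform acquisitions averaged per pixel.
#' @param noise_sigma Amplitude noise per acquisition, a.u.
#' @param include_echoes Passed to [transmit_through_slab()].
#' @param seed Integer seed for the noise stream.
#' @return A [raster_image()].
#' @export
scan_image <- function(map, reference, band = band_mask(1.5, 2),
                       averages = 12L, noise_sigma = 0, include_echoes = 8L,
                       seed = NULL) {
  stopifnot(inherits(map, "material_map"), inherits(reference, "thz_waveform"))
  rs <- compute_spectrum(reference)
  if (band$f_high > max(rs$frequency)) {
    stop("band extends beyond the simulated spectrum", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  sel <- which(in_band(rs$frequency, band))
  er <- Mod(rs$amplitude[sel])
  n <- length(reference$field)
  # per-material clean transmitted waveform
  clean <- lapply(map$materials, function(m) {
    transmit_through_slab(reference, m, include_echoes = include_echoes)$field
  })
  ny <- nrow(map$cells); nx <- ncol(map$cells)
  vals <- matrix(NA_real_, ny, nx)
  navg <- max(1L, as.integer(averages))
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      fld <- clean[[map$cells[iy, ix]]]
      if (noise_sigma > 0) {
        fld <- fld + stats::rnorm(n, 0, noise_sigma / sqrt(navg))
      }
      amp <- stats::fft(fld)[sel]
      vals[iy, ix] <- log(mean(Mod(amp) / er))
    }
  }
  raster_image(map$x, map$y, vals, band, map$pixel,
               n_waveform_averages = navg)
}

#' Detect inclusion candidates in a transmission image
#'
#' Flags pixels whose robust z-score of ln(T) (median/MAD) falls below
#' `-z_threshold`, groups them by 4-connectivity, and discards regions
#' smaller than `min_pixels`.  On a degenerate image with zero spread the
#' region list is empty.
#'
#' @param img A [raster_image()].
#' @param z_threshold Robust z cutoff (default 4).
#' @param min_pixels Minimum region area in pixels (default 4).
#' @return Data frame with one row per region: `label`, `area_px`,
#'   `centroid_x`, `centroid_y` (mm), `mean_ln_t`.
#' @export
detect_inclusions <- function(img, z_threshold = 4, min_pixels = 4L) {
  stopifnot(inherits(img, "raster_image"))
  v <- img$values
  med <- stats::median(v)
  madv <- stats::mad(v)
  empty <- data.frame(label = integer(0), area_px = integer(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      mean_ln_t = numeric(0))
  if (madv == 0) return(empty)
  flag <- (v - med) / madv < -z_threshold
  if (!any(flag)) return(empty)
  lab <- label_components(flag)
  out <- lapply(sort(unique(lab[lab > 0L])), function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < min_pixels) return(NULL)
    data.frame(label = id, area_px = nrow(idx),
               centroid_x = mean(img$x[idx[, 2]]),
               centroid_y = mean(img$y[idx[, 1]]),
               mean_ln_t = mean(v[idx]))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) return(empty)
  out$label <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# 4-connected component labeling of a logical matrix (iterative flood fill)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  ny <- nrow(mask); nx <- ncol(mask)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[i] != 0L || !mask[i]) next
      lab[i] <- cur
      r <- (i - 1L) %% ny + 1L
      c <- (i - 1L) %/% ny + 1L
      nb <- integer(0)
      if (r > 1L) nb <- c(nb, i - 1L)
      if (r < ny) nb <- c(nb, i + 1L)
      if (c > 1L) nb <- c(nb, i - ny)
      if (c < nx) nb <- c(nb, i + ny)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      stack <- c(stack, nb)
    }
  }
  lab
}

#' Write a raster image as a CSV matrix
#'
#' Rows correspond to y (first row = smallest y), columns to x; a `#`
#' header carries the band, pixel size and averaging provenance.
#'
#' @param img A [raster_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# band_THz=%.4g,%.4g pixel_mm=%.4g averages=%d",
                     img$band$f_low, img$band$f_high, img$pixel_size,
                     img$n_waveform_averages), con)
  utils::write.table(img$values, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
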