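#' Homogeneous slab material
#'
#' A plane-parallel slab characterised by its thickness and its complex
#' refractive index, given either as frequency-independent constants, as a
#' tabulated dispersion curve, or through a dielectric relaxation model
#' ([relaxation_parameters()]) from which the index is derived via
#' n = sqrt(eps) (branch with n_r > 0, n_i >= 0 under the
#' eps = eps_r - i eps_i convention).
#'
#' @param thickness Slab thickness L, mm (> 0).
#' @param n_r,n_i Constant real and imaginary refractive index (ignored when
#'   `relaxation` or `dispersion` is given).  `n_r > 0`, `n_i >= 0`.
#' @param relaxation Optional [relaxation_parameters()] object.
#' @param dispersion Optional data frame with columns `frequency` (THz),
#'   `n_r`, `n_i`; interpolated linearly in frequency.
#' @return An object of class `slab_material`.
#' @export
slab_material <- function(thickness, n_r = 1.6, n_i = 0,
                          relaxation = NULL, dispersion = NULL) {
  if (!is.numeric(thickness) || thickness <= 0) {
    stop("`thickness` must be positive (mm)", call. = FALSE)
  }
  if (is.null(relaxation) && is.null(dispersion)) {
    if (n_r <= 0) stop("`n_r` must be positive", call. = FALSE)
    if (n_i < 0) stop("`n_i` must be nonnegative", call. = FALSE)
  }
  if (!is.null(dispersion)) {
    stopifnot(all(c("frequency", "n_r", "n_i") %in% names(dispersion)))
    if (any(dispersion$n_r <= 0) || any(dispersion$n_i < 0)) {
      stop("tabulated dispersion must have n_r > 0, n_i >= 0", call. = FALSE)
    }
  }
  structure(
    list(thickness = thickness, n_r = n_r, n_i = n_i,
         relaxation = relaxation, dispersion = dispersion),
    class = "slab_material"
  )
}

#' Complex refractive index of a slab at given frequencies
#'
#' @param slab A [slab_material()].
#' @param frequency Frequencies, THz (nonnegative).
#' @return Complex vector n_r - i n_i.
#' @export
material_index <- function(slab, frequency) {
  stopifnot(inherits(slab, "slab_material"))
  if (!is.null(slab$relaxation)) {
    p <- slab$relaxation
    eps <- hn_complex(frequency, p$delta_eps, p$tau, p$eps_inf,
                      p$sigma_cc, p$sigma_cd)
    return(sqrt(eps))
  }
  if (!is.null(slab$dispersion)) {
    d <- slab$dispersion
    nr <- stats::approx(d$frequency, d$n_r, xout = frequency, rule = 2)$y
    ni <- stats::approx(d$frequency, d$n_i, xout = frequency, rule = 2)$y
    return(complex(real = nr, imaginary = -ni))
  }
  complex(real = rep(slab$n_r, length(frequency)),
          imaginary = rep(-slab$n_i, length(frequency)))
}

#' Synthetic single-cycle terahertz pulse
#'
#' Emulates the ~picosecond single-cycle pulses of an optoelectronic THz
#' emitter as a derivative-of-Gaussian: zero-mean, odd-symmetric about
#' `center_time`, with a smooth band-limited spectrum whose magnitude peaks
#' at `1/(pi * width)` THz.
#'
#' @param center_time Pulse center, ps.
#' @param width Pulse width parameter, ps (> 0); the underlying Gaussian has
#'   standard deviation `width / 2`.
#' @param amplitude Peak field amplitude, arbitrary units.
#' @param n_samples Number of samples in the trace.
#' @param dt Sample spacing, ps.
#' @return A [thz_waveform()] with role `"reference"`.
#' @export
synth_pulse <- function(center_time = 10, width = 0.5, amplitude = 1,
                        n_samples = 3200L, dt = 0.05) {
  if (width <= 0) stop("`width` must be positive", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  t <- (seq_len(n_samples) - 1L) * dt
  sigma <- width / 2
  support <- 8 * sigma
  if (center_time - support < t[1] || center_time + support > t[n_samples]) {
    stop("time window too short for the pulse support", call. = FALSE)
  }
  u <- (t - center_time) / sigma
  # derivative of a Gaussian, normalised so the extrema are +/- amplitude
  x <- -u * exp(-u^2 / 2) * amplitude * exp(0.5)
  thz_waveform(t, x, role = "reference")
}

# Full complex fft frequency axis (THz), with negative frequencies aliased,
# for an n-sample trace at spacing dt.
fft_frequencies <- function(n, dt) {
  k <- seq_len(n) - 1L
  k[k > n %/% 2] <- k[k > n %/% 2] - n
  k / (n * dt)
}

# Apply a transfer function H(f) (defined for f >= 0) to a real waveform in
# the frequency domain, preserving realness via Hermitian symmetry.
apply_transfer <- function(w, hfun) {
  n <- length(w$field)
  f <- fft_frequencies(n, w$dt)
  h <- hfun(abs(f))
  h[f < 0] <- Conj(h[f < 0])
  out <- Re(stats::fft(stats::fft(w$field) * h, inverse = TRUE)) / n
  out
}

# Normal-incidence field reflection coefficient going from medium 1 (index
# na) into medium 2 (index nb): r = (na - nb)/(na + nb).
fresnel_r <- function(na, nb) (na - nb) / (na + nb)

#' Transmit a reference pulse through a slab
#'
#' Frequency-domain forward model of normal-incidence transmission through a
#' plane-parallel slab in air: the reference spectrum is multiplied by
#' `t12 * t21 * exp(-i 2 pi f (n - 1) L / c0)` times a Fabry-Perot factor
#' truncated at `include_echoes` internal round trips (0 keeps the main
#' pulse only; `Inf` uses the closed-form full geometric series), then
#' inverse-transformed.  With n = n_r - i n_i, a positive n_i attenuates.
#'
#' @param reference A [thz_waveform()].
#' @param slab A [slab_material()].
#' @param include_echoes Number of internal round trips retained
#'   (nonnegative integer or `Inf`).
#' @return A [thz_waveform()] with role `"sample"`.
#' @export
transmit_through_slab <- function(reference, slab, include_echoes = 8L) {
  stopifnot(inherits(reference, "thz_waveform"), inherits(slab, "slab_material"))
  if (is.na(include_echoes) || include_echoes < 0) {
    stop("`include_echoes` must be >= 0", call. = FALSE)
  }
  L <- slab$thickness
  hfun <- function(f) {
    nn <- material_index(slab, f)
    if (any(Im(nn) > 1e-12)) {
      stop("non-physical slab: negative imaginary index (gain medium)",
           call. = FALSE)
    }
    t12 <- 2 / (1 + nn)
    t21 <- 2 * nn / (1 + nn)
    prop <- exp(-1i * 2 * pi * f * (nn - 1) * L / thz_c0)
    r21sq <- fresnel_r(nn, 1 + 0i)^2
    x <- r21sq * exp(-1i * 4 * pi * f * nn * L / thz_c0)
    fp <- if (is.infinite(include_echoes)) {
      1 / (1 - x)
    } else {
      m <- 0:include_echoes
      Reduce(`+`, lapply(m, function(k) x^k))
    }
    t12 * t21 * prop * fp
  }
  out <- apply_transfer(reference, hfun)
  thz_waveform(reference$time, out, role = "sample",
               n_averages = reference$n_averages)
}

#' External-reference-structure geometry
#'
#' The ERS consists of a partially reflecting beamsplitter and a mirror.  A
#' sample inserted between them splits the reflected waveform into four
#' principal pulses (beamsplitter back face, sample front face, sample back
#' face, mirror) whose arrival-time differences encode the sample thickness
#' and refractive index.
#'
#' @param rho Beamsplitter field reflectivity, in (0, 1).  The beamsplitter
#'   is modeled as an infinitesimally thin partial reflector with field
#'   transmissivity `sqrt(1 - rho^2)` (lossless).
#' @param L12 Air gap from beamsplitter back face to sample front face, mm.
#' @param L34 Air gap from sample back face to mirror, mm.
#' @param standoff One-way source-to-beamsplitter delay, ps; positions the
#'   first reflection inside the acquisition window.
#' @return An object of class `ers_geometry`.
#' @export
ers_geometry <- function(rho = 0.5, L12 = 5, L34 = 5, standoff = 0) {
  if (rho <= 0 || rho >= 1) stop("`rho` must lie in (0, 1)", call. = FALSE)
  if (L12 < 0 || L34 < 0) stop("gap lengths must be nonnegative", call. = FALSE)
  structure(list(rho = rho, L12 = L12, L34 = L34, standoff = standoff),
            class = "ers_geometry")
}

#' Simulate an ERS reflection waveform
#'
#' Without a sample the reflected trace carries two pulses separated by
#' `2 L14 / c0` where `L14 = L12 + L + L34` (beamsplitter-to-mirror
#' distance); with a sample, four principal pulses whose spacings are
#' `2 L12 / c0`, `2 n_r L / c0` and `2 L34 / c0`.  Pulse amplitudes and
#' signs follow the interface reflectivities (metallic mirror reflectivity
#' -1); propagation through the sample applies the full complex index, so a
#' lossy or dispersive slab attenuates and reshapes the interior pulses.
#'
#' @param reference A [thz_waveform()], the incident pulse.
#' @param geom An [ers_geometry()].
#' @param slab Optional [slab_material()]; `NULL` simulates the empty
#'   structure (sample gap replaced by air over the same thickness `L = 0`).
#' @param sample_thickness_gap With `slab = NULL`, an extra air path (mm)
#'   standing where the sample would be, so empty and loaded geometries
#'   share the same `L14`.
#' @return A [thz_waveform()] with role `"ers_sample"` or `"ers_empty"`.
#' @export
simulate_ers <- function(reference, geom, slab = NULL, sample_thickness_gap = 0) {
  stopifnot(inherits(reference, "thz_waveform"), inherits(geom, "ers_geometry"))
  rho <- geom$rho
  tau_bs <- sqrt(1 - rho^2)
  t_window <- reference$time[length(reference$time)] - reference$time[1]
  base <- 2 * geom$standoff

  if (is.null(slab)) {
    L14 <- geom$L12 + sample_thickness_gap + geom$L34
    d4 <- base + 2 * L14 / thz_c0
    if (d4 > t_window) stop("total ERS path exceeds the time window", call. = FALSE)
    hfun <- function(f) {
      ph <- function(d) exp(-1i * 2 * pi * f * d)
      rho * ph(base) + tau_bs^2 * (-1) * ph(d4)
    }
    out <- apply_transfer(reference, hfun)
    return(thz_waveform(reference$time, out, role = "ers_empty",
                        n_averages = reference$n_averages))
  }

  stopifnot(inherits(slab, "slab_material"))
  L <- slab$thickness
  d1 <- base
  d2 <- base + 2 * geom$L12 / thz_c0
  # worst-case arrival (mirror pulse), using the DC index for the check
  n_dc <- Re(material_index(slab, 0))
  d4max <- d2 + 2 * n_dc * L / thz_c0 + 2 * geom$L34 / thz_c0
  if (d4max > t_window) stop("total ERS path exceeds the time window", call. = FALSE)
  hfun <- function(f) {
    nn <- material_index(slab, f)
    ph <- function(d) exp(-1i * 2 * pi * f * d)
    prop_s <- exp(-1i * 4 * pi * f * nn * L / thz_c0)  # round trip inside slab
    r12 <- fresnel_r(1 + 0i, nn)
    r21 <- fresnel_r(nn, 1 + 0i)
    t12 <- 2 / (1 + nn)
    t21 <- 2 * nn / (1 + nn)
    p1 <- rho * ph(d1)
    p2 <- tau_bs^2 * r12 * ph(d2)
    p3 <- tau_bs^2 * t12 * t21 * r21 * prop_s * ph(d2)
    p4 <- tau_bs^2 * (t12 * t21)^2 * (-1) * prop_s *
      ph(d2 + 2 * geom$L34 / thz_c0)
    p1 + p2 + p3 + p4
  }
  out <- apply_transfer(reference, hfun)
  thz_waveform(reference$time, out, role = "ers_sample",
               n_averages = reference$n_averages)
}

#' Add measurement noise to a waveform
#'
#' Adds seeded white Gaussian amplitude noise and a seeded global timing
#' shift (drawn once per call, normal with standard deviation
#' `timing_jitter`, applied as a circular frequency-domain shift).
#' Deterministic for a fixed seed.
#'
#' @param w A [thz_waveform()].
#' @param sigma Amplitude noise standard deviation, a.u. (>= 0).
#' @param timing_jitter Timing shift standard deviation, ps (>= 0).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A [thz_waveform()].
#' @export
add_noise <- function(w, sigma, timing_jitter = 0, seed = NULL) {
  stopifnot(inherits(w, "thz_waveform"))
  if (sigma < 0 || timing_jitter < 0) {
    stop("`sigma` and `timing_jitter` must be nonnegative", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  x <- w$field
  if (timing_jitter > 0) {
    shift <- stats::rnorm(1, 0, timing_jitter)
    n <- length(x)
    f <- fft_frequencies(n, w$dt)
    x <- Re(stats::fft(stats::fft(x) * exp(-1i * 2 * pi * f * shift),
                       inverse = TRUE)) / n
  }
  if (sigma > 0) x <- x + stats::rnorm(length(x), 0, sigma)
  thz_waveform(w$time, x, role = w$role, n_averages = w$n_averages)
}

#' Inclusion disk feature
#'
#' @param x,y Center, mm.
#' @param radius Radius, mm.
#' @param material [slab_material()] filling the disk.
#' @return Feature object for [make_material_map()].
#' @export
inclusion_disk <- function(x, y, radius, material) {
  stopifnot(radius > 0, inherits(material, "slab_material"))
  structure(list(kind = "disk", x = x, y = y, radius = radius,
                 material = material), class = "map_feature")
}

#' Flow-line feature
#'
#' A band of perturbed material along a straight segment, emulating resin
#' flow lines.
#'
#' @param x0,y0,x1,y1 Segment end points, mm.
#' @param width Full width of the band, mm.
#' @param material [slab_material()] along the line.
#' @return Feature object for [make_material_map()].
#' @export
flow_line <- function(x0, y0, x1, y1, width, material) {
  stopifnot(width > 0, inherits(material, "slab_material"))
  structure(list(kind = "line", x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                 width = width, material = material), class = "map_feature")
}

#' Synthetic 2-D material map for raster imaging
#'
#' A rectangular grid of slab materials standing in for a polished amber
#' slice with embedded features.  Features are painted in order (a later
#' feature wins where they overlap); ground-truth feature annotations are
#' kept for test harnesses.
#'
#' @param width,height Map extent, mm.
#' @param pixel Pixel size, mm; must divide `width` and `height`.
#' @param matrix_material [slab_material()] of the background matrix.
#' @param features List of [inclusion_disk()] / [flow_line()] features.
#' @return An object of class `material_map`: list with `x`, `y` pixel-center
#'   coordinates, a `cells` integer matrix (rows = y, columns = x) indexing
#'   `materials`, the `materials` list, `pixel`, and the `features` list.
#' @export
make_material_map <- function(width, height, pixel, matrix_material,
                              features = list()) {
  stopifnot(inherits(matrix_material, "slab_material"), pixel > 0)
  nx <- width / pixel
  ny <- height / pixel
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9) {
    stop("`pixel` must divide `width` and `height`", call. = FALSE)
  }
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))
  x <- (seq_len(nx) - 0.5) * pixel
  y <- (seq_len(ny) - 0.5) * pixel
  cells <- matrix(1L, nrow = ny, ncol = nx)
  materials <- list(matrix_material)
  for (ft in features) {
    stopifnot(inherits(ft, "map_feature"))
    materials <- c(materials, list(ft$material))
    id <- length(materials)
    if (ft$kind == "disk") {
      if (ft$x < 0 || ft$x > width || ft$y < 0 || ft$y > height) {
        stop("feature center out of map bounds", call. = FALSE)
      }
      dx <- outer(rep(1, ny), x) - ft$x
      dy <- outer(y, rep(1, nx)) - ft$y
      cells[dx^2 + dy^2 <= ft$radius^2] <- id
    } else {
      if (min(ft$x0, ft$x1) < 0 || max(ft$x0, ft$x1) > width ||
          min(ft$y0, ft$y1) < 0 || max(ft$y0, ft$y1) > height) {
        stop("feature end point out of map bounds", call. = FALSE)
      }
      px <- outer(rep(1, ny), x); py <- outer(y, rep(1, nx))
      vx <- ft$x1 - ft$x0; vy <- ft$y1 - ft$y0
      len2 <- vx^2 + vy^2
      tproj <- pmin(pmax(((px - ft$x0) * vx + (py - ft$y0) * vy) / len2, 0), 1)
      d2 <- (px - (ft$x0 + tproj * vx))^2 + (py - (ft$y0 + tproj * vy))^2
      cells[d2 <= (ft$width / 2)^2] <- id
    }
  }
  structure(list(x = x, y = y, cells = cells, materials = materials,
                 pixel = pixel, features = features),
            class = "material_map")
}

#' @export
print.material_map <- function(x, ...) {
  cat(sprintf("<material_map> %d x %d pixels at %.3g mm (%g x %g mm), %d feature(s)\n",
              ncol(x$cells), nrow(x$cells), x$pixel,
              ncol(x$cells) * x$pixel, nrow(x$cells) * x$pixel,
              length(x$features)))
  invisible(x)
}
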