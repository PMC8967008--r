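test_that("phase difference is zero for identical spectra and recovers the slab phase", {
  ref <- std_pulse()
  rs <- compute_spectrum(ref)
  band <- band_mask(0.2, 2)
  ph0 <- phase_difference(rs, rs, band)
  expect_equal(max(abs(ph0$delta_phi)), 0, tolerance = 1e-12)
  # slab n_r = 1.6, L = 8 mm: delta_phi(f) = 2 pi f (n-1) L / c0
  smp <- transmit_through_slab(ref, slab_material(8, n_r = 1.6),
                               include_echoes = 0L)
  ph <- phase_difference(compute_spectrum(smp), rs, band)
  i05 <- which.min(abs(ph$frequency - 0.5))
  expected <- 2 * pi * 0.5 * 0.6 * 8 / thz_c0          # = 50.3 rad
  expect_equal(ph$delta_phi[i05], expected, tolerance = 1e-3)
  # whole curve is linear in f
  expect_equal(ph$delta_phi,
               2 * pi * ph$frequency * 0.6 * 8 / thz_c0, tolerance = 1e-6)
  expect_error(phase_difference(rs, rs, band_mask(0.2, 0.21)), "5 grid points")
})

test_that("phase anchoring is invariant to a global 2 pi branch shift", {
  ref <- std_pulse()
  rs <- compute_spectrum(ref)
  smp <- transmit_through_slab(ref, slab_material(8, n_r = 1.6),
                               include_echoes = 0L)
  ss <- compute_spectrum(smp)
  band <- band_mask(0.2, 2)
  ph <- phase_difference(ss, rs, band)
  # multiplying the sample spectrum by exp(-2 pi i k) leaves the wrapped
  # phases, and hence the anchored unwrapped output, unchanged
  ss2 <- ss
  ss2$amplitude <- ss$amplitude * exp(-2i * pi * 3)
  ph2 <- phase_difference(ss2, rs, band)
  expect_equal(ph2$delta_phi, ph$delta_phi, tolerance = 1e-9)
})

test_that("real index inverts the phase relation", {
  expect_equal(real_refractive_index(list(frequency = 1, delta_phi = 0), L = 5), 1)
  dphi <- 2 * pi * 0.5 * 0.6 * 8 / thz_c0
  expect_equal(real_refractive_index(list(frequency = 0.5, delta_phi = dphi),
                                     L = 8), 1.6, tolerance = 1e-12)
  # doubling both delta_phi and L leaves n_r unchanged
  expect_equal(real_refractive_index(list(frequency = 0.5, delta_phi = 2 * dphi),
                                     L = 16), 1.6, tolerance = 1e-12)
  expect_error(real_refractive_index(list(frequency = 0.5, delta_phi = 1), L = 0),
               "positive")
  expect_error(real_refractive_index(list(frequency = 0, delta_phi = 1), L = 1),
               "zero frequency")
})

test_that("Fresnel transmission coefficients match the closed forms", {
  tc <- fresnel_coefficients(1)
  expect_equal(tc$t12, 1); expect_equal(tc$t21, 1)
  tc <- fresnel_coefficients(1.6)
  expect_equal(tc$t12, 2 / 2.6, tolerance = 1e-12)     # 0.7692
  expect_equal(tc$t21, 3.2 / 2.6, tolerance = 1e-12)   # 1.2308
  expect_error(fresnel_coefficients(-1), "positive")
})

test_that("imaginary index recovers absorption and obeys log linearity", {
  ref <- std_pulse()
  rs <- compute_spectrum(ref)
  band <- band_mask(0.2, 2)
  # lossless: |E_S| = |E_R| t12 t21 exactly cancels the Fresnel factor
  slab0 <- slab_material(3.91, n_r = 1.6, n_i = 0)
  ss0 <- compute_spectrum(transmit_through_slab(ref, slab0, include_echoes = 0L))
  nr <- rep(1.6, sum(rs$frequency >= 0.2 & rs$frequency <= 2))
  r0 <- imaginary_refractive_index(ss0, rs, nr, L = 3.91, band = band)
  expect_equal(max(abs(r0$n_i)), 0, tolerance = 1e-9)
  # constant n_i = 0.01 recovered within 1e-3 over the band
  slab1 <- slab_material(3.91, n_r = 1.6, n_i = 0.01)
  ss1 <- compute_spectrum(transmit_through_slab(ref, slab1, include_echoes = 0L))
  r1 <- imaginary_refractive_index(ss1, rs, nr, L = 3.91, band = band)
  expect_lt(max(abs(r1$n_i - 0.01)), 1e-3)
  expect_identical(r1$n_clipped, 0L)
  # halving |E_S| adds c0 ln2 / (omega L) uniformly
  ss2 <- ss1; ss2$amplitude <- ss1$amplitude / 2
  r2 <- imaginary_refractive_index(ss2, rs, nr, L = 3.91, band = band)
  expect_equal(r2$n_i - r1$n_i,
               thz_c0 * log(2) / (2 * pi * r1$frequency * 3.91),
               tolerance = 1e-9)
})

test_that("permittivity/index conversion is exact and invertible", {
  band <- band_mask(0.1, 2)
  p <- permittivity_from_index(1, 1.6, 0, band)
  expect_equal(p$eps_r, 2.56); expect_equal(p$eps_i, 0)
  p <- permittivity_from_index(1, 1.6, 0.05, band)
  expect_equal(p$eps_r, 2.5575, tolerance = 1e-12)
  expect_equal(p$eps_i, 0.16, tolerance = 1e-12)
  # complex square root restores (n_r, n_i)
  nn <- sqrt(complex(real = p$eps_r, imaginary = -p$eps_i))
  expect_equal(Re(nn), 1.6, tolerance = 1e-12)
  expect_equal(-Im(nn), 0.05, tolerance = 1e-12)
})

test_that("extraction round-trips a Debye slab within 1% (0.1% echo-free)", {
  ref <- std_pulse()
  p <- relaxation_parameters("debye", delta_eps = 0.2, tau = 0.3, eps_inf = 2.3)
  slab <- slab_material(3.91, relaxation = p)
  band <- band_mask(0.2, 2)
  # with echoes and fringe smoothing
  smp <- transmit_through_slab(ref, slab, include_echoes = 8L)
  perm <- extract_permittivity(smp, ref, L = 3.91, band = band,
                               smooth_window = 11L)
  truth <- evaluate_model(p, perm$frequency)
  expect_lt(max(abs(perm$eps_r - truth$eps_r) / truth$eps_r), 0.01)
  # echo-free, unsmoothed: an order of magnitude tighter
  smp0 <- transmit_through_slab(ref, slab, include_echoes = 0L)
  perm0 <- extract_permittivity(smp0, ref, L = 3.91, band = band,
                                smooth_window = 1L)
  truth0 <- evaluate_model(p, perm0$frequency)
  expect_lt(max(abs(perm0$eps_r - truth0$eps_r) / truth0$eps_r), 0.001)
  expect_lt(max(abs(perm0$eps_i - truth0$eps_i)), 0.001)
  expect_identical(attr(perm0, "n_clipped"), 0L)
})

test_that("extracted permittivity is independent of sample thickness", {
  ref <- std_pulse()
  p <- baltic_relaxation()
  band <- band_mask(0.2, 2)
  perms <- lapply(c(3.91, 7.0), function(L) {
    smp <- transmit_through_slab(ref, slab_material(L, relaxation = p),
                                 include_echoes = 0L)
    extract_permittivity(smp, ref, L = L, band = band, smooth_window = 1L)
  })
  expect_equal(perms[[1]]$frequency, perms[[2]]$frequency)
  expect_lt(max(abs(perms[[1]]$eps_r - perms[[2]]$eps_r) / perms[[1]]$eps_r),
            0.005)
  expect_lt(max(abs(perms[[1]]$eps_i - perms[[2]]$eps_i)), 0.005)
})

test_that("permittivity CSV round-trips through the standard layout", {
  f <- seq(0.2, 2, by = 0.01)
  truth <- evaluate_model(baltic_relaxation(), f)
  path <- withr::local_tempfile(fileext = ".csv")
  write_permittivity(truth, path, comments = "fixture")
  back <- load_permittivity(path)
  expect_equal(back$frequency, f, tolerance = 1e-9)
  expect_equal(back$eps_r, truth$eps_r, tolerance = 1e-9)
  expect_equal(back$eps_i, truth$eps_i, tolerance = 1e-9)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(load_permittivity(bad), "freq_THz")
})
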