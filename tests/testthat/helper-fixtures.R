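# Shared fixture builders: the standard instrument emulation is a 160 ps
# window at 0.05 ps sampling (3200 samples) with a single-cycle pulse.

std_pulse <- function(width = 0.5, center = 10) {
  synth_pulse(center_time = center, width = width, n_samples = 3200L, dt = 0.05)
}

# Baltic-amber-like slab: thickness and nominal index from time-of-flight
# characterisation of clear Baltic amber, with a Cole-Davidson-type loss.
baltic_relaxation <- function() {
  relaxation_parameters("havriliak_negami", delta_eps = 0.215, tau = 0.202,
                        eps_inf = 2.4, sigma_cc = 0.9, sigma_cd = 0.5)
}

baltic_slab <- function() {
  slab_material(thickness = 3.91, relaxation = baltic_relaxation())
}

std_ers_geometry <- function() ers_geometry(rho = 0.5, L12 = 5, L34 = 5, standoff = 3)

# time after which the sample trace contains only Fabry-Perot echoes,
# for a slab with DC index n and thickness L, pulse centered at `center`
first_echo_gate <- function(center, n_dc, L, margin = 0.85) {
  center + (n_dc - 1) * L / thz_c0 + margin * 2 * n_dc * L / thz_c0
}

# independent Debye permittivity oracle (single relaxation time)
debye_eps_oracle <- function(f, delta_eps, tau, eps_inf) {
  w <- 2 * pi * f
  eps_inf + delta_eps / (1 + 1i * w * tau)
}

# noisy Cole-Cole loss spectrum used in the fit-recovery studies
cc_noisy_perm <- function(seed, delta_eps = 0.2, tau = 0.2, sigma_cc = 0.8,
                          noise = 0.01, n = 150L, f_lo = 0.15, f_hi = 2) {
  f <- seq(f_lo, f_hi, length.out = n)
  p <- relaxation_parameters("cole_cole", delta_eps = delta_eps, tau = tau,
                             sigma_cc = sigma_cc)
  truth <- evaluate_model(p, f)
  set.seed(seed)
  y <- truth$eps_i * (1 + noise * stats::rnorm(n))
  permittivity_spectrum(f, truth$eps_r, y, band_mask(f_lo, f_hi))
}

# three-disk raster fixture (geometry of the standard imaging scenario)
three_disk_map <- function(width = 29, height = 21, pixel = 0.2) {
  matrix_m <- slab_material(5, n_r = 1.6, n_i = 0.002)
  inc <- slab_material(5, n_r = 1.62, n_i = 0.02)
  make_material_map(width, height, pixel, matrix_m, features = list(
    inclusion_disk(6, 6, 1.0, inc),
    inclusion_disk(15, 12, 0.8, inc),
    inclusion_disk(23, 16, 1.2, inc)))
}

# amber-like reference library (5 entries) plus a high-loss counterfeit
amberlike_entries <- function(f = seq(0.2, 2, by = 0.0125)) {
  specs <- amberthz:::amberlike_library_specs()
  lapply(specs, function(fn) fn(f))
}
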