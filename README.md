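# amberthz

Terahertz time-domain spectroscopy (THz-TDS) analysis of fossil amber, for
paleontologists, conservators and spectroscopists who want to inspect and
characterise resin samples non-destructively. The package turns raw
picosecond pulse waveforms into material quantities and images:

* **Permittivity extraction** — from a transmitted/reference waveform pair,
  the complex refractive index via
  `n_r = 1 + c0 Δφ/(ωL)` and
  `n_i = (c0/ωL) ln(|E_R|/|E_S| · t12 t21)` (Fresnel-corrected), and the
  permittivity `ε = ε_r − iε_i` with `ε_r = n_r² − n_i²`, `ε_i = 2 n_r n_i`,
  over an automatically selected usable band with Fabry–Pérot fringes
  suppressed by a moving average.
* **Time-of-flight gauging** — sample thickness and refractive index
  measured simultaneously against an external reference structure
  (beamsplitter + mirror): `L = (c0/2)[(t4°−t1°) − (t2−t1) − (t4−t3)]`,
  `n_r = c0(t3−t2)/(2L)`, with closed-form uncertainty propagation from
  the pulse-timing uncertainties.
* **Dielectric relaxation fitting** — the Havriliak–Negami family
  `ε(ω) = ε∞ + Δε / [1 + (iωτ)^σCC]^σCD` and its Debye, Cole-Cole and
  Cole-Davidson limits, fit to the loss spectrum by deterministic
  multi-start bounded least squares, with robust 95% CIs, R², and a
  residual-randomness runs test feeding a documented model ranking.
* **Transmission imaging** — per-pixel band-averaged `ln |E_S/E_R|`
  (default 1.5–2 THz) raster images and robust-z connected-component
  detection of inclusions.
* **Counterfeit screening** — permittivity-distance comparison of a query
  sample against a reference library, flagging grossly dissimilar
  materials such as synthetic resins.

A forward simulator (`synth_pulse()`, `transmit_through_slab()`,
`simulate_ers()`, `make_material_map()`, `scan_image()`) generates every
input from known ground truth, so the full pipeline is testable without
instrument data. See the methods vignette
(`vignettes/amber-thz-methods.Rmd`) for the models, conventions and
numerical choices.

## Worked example

Simulate a Baltic-amber-like slab (3.91 mm, Cole-Davidson loss), extract
its permittivity, fit relaxation models, and gauge it by time-of-flight:

```r
library(amberthz)

ref  <- synth_pulse(center_time = 10, width = 0.5)      # 160 ps window
p    <- relaxation_parameters("cole_davidson", delta_eps = 0.215,
                              tau = 0.202, eps_inf = 2.4, sigma_cd = 0.444)
slab <- slab_material(thickness = 3.91, relaxation = p)
smp  <- transmit_through_slab(ref, slab)                # with FP echoes

perm <- extract_permittivity(smp, ref, L = 3.91, band = band_mask(0.2, 2))
perm
#> <permittivity_spectrum> 289 points, band [0.2, 2] THz, smooth=11
#>   in-band eps_r: 2.519..2.614   eps_i: 0.025..0.07103

fit_imaginary(perm, "cole_davidson")
#> <relaxation_fit> cole_davidson  R^2=0.9986  n=289  converged=TRUE
#>   delta_eps  0.21878  (95% CI +/- 0.00541)
#>   tau        0.20579  (95% CI +/- 0.00553)
#>   sigma_cd   0.43062  (95% CI +/- 0.0185)

compare_models(list(fit_imaginary(perm, "debye"),
                    fit_imaginary(perm, "cole_davidson")))
#>           model r_squared mean_rel_ci       runs_p converged rank
#> 1 cole_davidson 0.9985647 0.031510100 3.727934e-54      TRUE    1
#> 2         debye 0.9809752 0.006170934 2.707725e-63      TRUE    2
```

The extraction recovers the generating parameters (Δε = 0.215, τ = 0.202 ps,
σ_CD = 0.444) to a few percent through the full forward/inverse chain —
residual deviations come from the smoothed Fabry–Pérot fringes, which also
drive the runs-test p-values toward zero — and the asymmetric-broadening
model clearly outranks Debye, the qualitative signature of amber loss
spectra.

```r
geom   <- ers_geometry(L12 = 5, L34 = 5, standoff = 3)
empty  <- simulate_ers(ref, geom, sample_thickness_gap = 3.91)
loaded <- simulate_ers(ref, geom, slab_material(3.91, n_r = 1.6))
tm <- measure_ers(empty, loaded, ref,
                  sigma_t = c(t14o = 0.02, t12 = 0.02, t23 = 0.02, t34 = 0.02))
L  <- ers_thickness(tm)
nr <- ers_refractive_index(tm, L)
u  <- index_uncertainty(tm)
cat(sprintf("L = %.3f mm, n_r = %.4f +/- %.4f\n", L, nr, u$absolute))
#> L = 3.910 mm, n_r = 1.6000 +/- 0.0023
```

A shell entry point wrapping the same stages
(`simulate | extract | tof | fit | image | compare`) is installed at
`system.file("cli", "amberthz.R", package = "amberthz")`; see `?thz_cli`.

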