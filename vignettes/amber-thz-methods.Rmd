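---
title: "Methods: terahertz time-domain analysis of fossil amber"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: terahertz time-domain analysis of fossil amber}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amberthz)
```

## The measurement and the models

Terahertz time-domain spectroscopy (THz-TDS) probes a sample with
single-cycle electromagnetic pulses of roughly picosecond duration and
records the transmitted (or reflected) electric field as a function of time.
Fossil resin is fairly transparent between about 0.1 and 2.5 THz, which
makes THz-TDS attractive for two complementary tasks this package
implements: *non-destructive imaging* of inclusions, flow lines and cracks
inside opaque or partially opaque amber, and *dielectric characterisation* —
extracting the complex permittivity and relaxation dynamics of the
polymerised resin, which carries information about its material state.

Units are ps / THz / mm throughout, with the vacuum speed of light
`thz_c0` = 0.299792458 mm/ps. Fields follow the $e^{+i\omega t}$
convention, so the complex index is $\tilde n = n_r - i n_i$ and the
permittivity $\varepsilon = \varepsilon_r - i\varepsilon_i$, with
$n_i \ge 0$ and $\varepsilon_i \ge 0$ for passive, absorbing media. Note
that under the alternative $(n_r + i n_i)^2$ sign layout one finds
$\varepsilon_i = -2 n_r n_i$; we deliberately use the absorbing-medium
convention $\varepsilon_i = +2 n_r n_i$ so that positive loss is positive.

### Transmission spectroscopy

From a sample/reference waveform pair, `extract_permittivity()` applies the
classical slab inversion. With $\Delta\phi(\omega)$ the unwrapped phase of
$E_R/E_S$ and $L$ the slab thickness,

$$n_r(\omega) = 1 + \frac{c_0\,\Delta\phi(\omega)}{\omega L},\qquad
  n_i(\omega) = \frac{c_0}{\omega L}\,
  \ln\!\left(\frac{|E_R(\omega)|}{|E_S(\omega)|}\,t_{12} t_{21}\right),$$

where $t_{12} = 2/(1+n_r)$ and $t_{21} = 2 n_r/(n_r+1)$ are the
normal-incidence Fresnel field-transmission factors correcting the
amplitude ratio for reflection losses at the two faces, and
$\varepsilon_r = n_r^2 - n_i^2$, $\varepsilon_i = 2 n_r n_i$.

Multiple internal reflections between the slab's parallel faces
(Fabry–Pérot echoes) put oscillatory fringes on the extracted spectra. The
standard treatment — and the default here — is a centred moving average
(default 11 points, configurable 1–15) applied to $\varepsilon_r$ and
$\varepsilon_i$ after inversion. A `time_gate` option that truncates the
sample trace before the first echo is provided for validation work, where
it is essentially exact on synthetic data.

### Time-of-flight with an external reference structure

Caliper thickness is the dominant uncertainty of the slab inversion, so the
package also implements the external-reference-structure (ERS) method: a
beamsplitter and mirror bracket the sample, and the reflected trace carries
four principal pulses (beamsplitter back face, sample front, sample back,
mirror). With the empty-structure arrivals $t_1^o, t_4^o$ and loaded
arrivals $t_1\ldots t_4$:

$$L_{14} = \tfrac{c_0}{2}(t_4^o - t_1^o),\qquad
  L = \tfrac{c_0}{2}\left[(t_4^o - t_1^o) - (t_2-t_1) - (t_4-t_3)\right],
  \qquad n_r = \frac{c_0 (t_3 - t_2)}{2L}.$$

The thickness is independent of the sample's refractive index, and the
index comes out at the pulse's spectral peak (nominally ~0.2 THz).
First-order error propagation gives

$$\left(\frac{\sigma_n}{n}\right)^2 =
  \left(\frac{\sigma_{t_{23}}}{t_{23}}\right)^2 +
  \frac{\sigma^2_{t_{14}^o} + \sigma^2_{t_{12}} + \sigma^2_{t_{34}}}
       {(t_{14}^o - t_{12} - t_{34})^2},$$

implemented in `index_uncertainty()` and cross-checked in the tests against
$10^5$-draw Monte-Carlo propagation (agreement well below 1%). With all
interval uncertainties at the typical 0.02 ps this evaluates to an absolute
index uncertainty of about 0.0023 for a 3.91 mm slab of index 1.600 — the
same order as the ±0.003 precision quoted for instrument practice.

Arrival times are measured by `deconvolve()` + `detect_peaks()`:
frequency-domain division stabilised by a Wiener-type regulariser
(`reg` relative to peak reference power, default $10^{-4}$), followed by
three-point parabolic refinement of each $|$response$|$ maximum to
sub-sample precision. The impulse-response lag axis runs from zero to the
full window because reflection delays are nonnegative; a centred axis would
wrap the mirror pulse, which arrives after half the 160 ps window.

### Dielectric relaxation models

`evaluate_model()` and `fit_imaginary()` implement the Havriliak–Negami
family

$$\varepsilon(\omega) = \varepsilon_\infty +
  \frac{\varepsilon_s - \varepsilon_\infty}
       {\left[1 + (i\omega\tau)^{\sigma_{CC}}\right]^{\sigma_{CD}}},$$

whose limits are Debye ($\sigma_{CC}=\sigma_{CD}=1$), Cole–Cole
($\sigma_{CD}=1$; symmetric broadening of the relaxation-time
distribution) and Cole–Davidson ($\sigma_{CC}=1$; asymmetric broadening).
Principal branches are used for the complex powers; the loss peak of a
Debye medium then falls at $f = 1/(2\pi\tau)$ with height
$\Delta\varepsilon/2$, which the tests verify on dense grids.

Fitting targets the loss $\varepsilon_i(\omega)$ only.
$\varepsilon_\infty$ cancels out of the imaginary part and is therefore
*not* a fitted parameter; when needed it should be estimated from the
high-frequency real permittivity. The optimiser is bounded
Levenberg–Marquardt (`minpack.lm`) from a fixed multi-start grid
($\tau \in \{0.05, 0.1, 0.2, 0.5, 1\}$ ps ×
exponents $\in \{0.3, 0.6, 0.9, 1.0\}$; bounds
$\Delta\varepsilon \in (0, 10]$, $\tau \in [0.01, 10]$ ps, exponents
$\in (0.05, 1]$). Including 1.0 in the exponent grid guarantees the richer
models can reach each nested model's optimum, which is why the best-fit
$R^2$ ordering HN ≥ Cole–Cole ≥ Debye holds on every dataset to optimiser
tolerance. There is no random initialisation, so fits are deterministic.

95% confidence half-widths use a heteroscedasticity-robust (sandwich)
covariance, $(J^{\top}J)^{-1} J^{\top}\mathrm{diag}(r^2) J (J^{\top}J)^{-1}$
with an HC1 small-sample factor and a $t$ quantile on $n-p$ degrees of
freedom. The robust form was chosen because the noise on extracted loss
spectra scales roughly with the signal; a pooled-variance Gauss–Newton
covariance over-covers by a few percent under exactly that noise, while the
sandwich interval stays at nominal coverage in the package's recovery
studies (94–95% empirically over 1000 replicates).

`compare_models()` ranks fits the way a practitioner reads them: converged
first, then $R^2$; $R^2$ ties closer than 0.005 are broken by mean relative
CI width, then by the Wald–Wolfowitz runs-test p-value of the residual
signs (`residual_randomness()`; exact conditional run-count distribution up
to 50 signed residuals, normal approximation beyond), and finally by model
tag for determinism.

### Imaging and screening

`scan_image()` rasters a material map and records per pixel
$\ln T = \ln \overline{|E_S/E_R|}$, the band-averaged (unweighted mean,
default 1.5–2 THz) field-magnitude transmission — the contrast mechanism
by which inclusions, which scatter and absorb, darken the image.
`detect_inclusions()` flags pixels whose robust z-score (median/MAD) of
$\ln T$ drops below −4, groups them by 4-connectivity and drops regions
under 4 pixels.

`screen_sample()` compares a query permittivity spectrum against a
reference library using band-overlapped mean absolute differences of
$\varepsilon_r$ and $\varepsilon_i$ (linear interpolation onto the coarser
grid, no extrapolation). A sample is flagged when its best combined score
exceeds `flag_factor` (default 2) times the library's median pairwise
score; a single-entry library falls back to a documented absolute
threshold of 0.2. The score and thresholds are screening conventions of
this package, stated in output provenance — a flag is a prompt for further
analysis, not an authentication verdict.

## The synthetic-data generator

No instrument waveforms ship with the package, so `synth_pulse()`,
`transmit_through_slab()`, `simulate_ers()`, `add_noise()` and
`make_material_map()` form a forward simulator with known ground truth.
It emulates a transmission/reflection THz-TDS instrument: a 160 ps
acquisition window at 0.05 ps sampling, a zero-mean derivative-of-Gaussian
single-cycle pulse, band-limited power that decays smoothly at high
frequency, slab transmission with the full complex-index Fresnel factors
and a Fabry–Pérot series truncated at a configurable number of round trips
(default 8; residual below $10^{-6}$ for amber-like indices, `Inf` selects
the closed-form series), ERS reflections with an idealised thin
beamsplitter (field reflectivity 0.5, lossless), and raster maps with
0.2 mm pixels and 12 waveform averages per pixel, in the geometry of a
29 × 21 mm scan.

The default pulse width parameter is 0.5 ps, placing the spectral peak
near 0.6 THz. This is chosen so the simulated spectrum retains usable
power across the full 0.2–2 THz analysis band in double precision; the
hardware this emulates peaks nearer 0.2 THz, but its exact spectral shape
is not modelled. Other simplifications, and what they mean for the tests:

* No Gaussian-beam propagation, diffraction, or aperture clipping — the
  low/high-frequency band limits that these effects impose in practice are
  represented only through `usable_band()`'s dynamic-range criterion.
  Passing tests therefore say nothing about small-sample aperture
  artifacts.
* Noise is white and additive with an optional global timing jitter;
  real systems add correlated drift, etalon ripple from optics, and
  amplitude-dependent shot noise.
* The beamsplitter is infinitesimally thin; a real substrate adds its own
  echo family to ERS traces.
* Averaging `n` acquisitions is simulated as one noise draw at
  $\sigma/\sqrt{n}$, which is exact for additive white noise and much
  faster.

Because the generator's dispersion comes from the same Havriliak–Negami
family the fitter estimates, fit-recovery results demonstrate correctness
of the estimation machinery, not the adequacy of those models for any
particular resin.

## Numerical choices and degenerate inputs

* **Band selection.** The noise floor is the median reference magnitude
  above 3 THz (beyond the source band); both spectra must clear it by
  `dynamic_range_db` (default 20 dB in field amplitude), and the lower
  edge never drops below 0.1 THz, where these sources emit almost no
  power. An empty band is an error, not an empty result.
* **Phase unwrapping.** $\Delta\phi$ is unwrapped along ascending
  frequency in-band, then the absolute $2\pi k$ branch is fixed by
  requiring a linear fit over the lowest quartile of the band to
  extrapolate nearest zero at zero frequency (a transparent slab's phase
  delay is proportional to frequency). Bands narrower than 5 grid points
  are rejected.
* **Clipping.** Negative extracted $n_i$ (noise or fringe residue) is
  clipped to zero and counted; the count is attached to the result and is
  zero on clean simulations.
* **Smoothing windows** must be odd; edges use shrinking symmetric
  windows, so the series length is preserved and the value range never
  widens.
* **Peak detection** requires the expected pulse count at the requested
  separation and fails loudly otherwise; a flat parabola denominator
  falls back to the grid position.
* **Runs test** on residuals that are all one sign returns p = 0 with a
  `degenerate` flag rather than erroring.
* **Model limits.** The HN family approaches $\varepsilon_s$ and
  $\varepsilon_\infty$ as $(\omega\tau)^{\pm\sigma}$, so tests bound the
  deviation at finite frequency by the leading asymptotic term; only the
  Debye limit reaches $10^{-9}$ closeness at numerically reachable
  frequencies.

## Problem sizes used by the test and acceptance runs

All studies are sized for a single CPU desk run: 3200-sample waveforms;
150-point loss spectra with 1% multiplicative noise; 200 seeds for the
parameter-recovery/coverage study and 100 for model ranking; $10^5$
Monte-Carlo draws for uncertainty propagation and 1000 repeats for the
empirical index spread; a full 145 × 105-pixel raster (29 × 21 mm at
0.2 mm) with three absorbing disks for imaging; 1000 null replicates
(n = 200) for runs-test calibration. The complete suite runs in well under
a minute.

## Known limitations

Single homogeneous slabs only (no multilayers, no reflection-mode
spectroscopy); the four principal ERS pulses only; no Kramers–Kronig
consistency enforcement between $\varepsilon_r$ and $\varepsilon_i$; no
sum-of-modes relaxation or temperature dependence; screening is a
distance heuristic against a user-supplied library and inherits whatever
band limitations that library has.
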