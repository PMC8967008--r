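Package: amberthz
Title: Terahertz Time-Domain Spectroscopy of Fossil Amber
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for terahertz time-domain spectroscopy (THz-TDS)
    of fossil resins. Extracts frequency-dependent complex refractive index and
    permittivity from transmitted picosecond pulse waveforms with Fresnel
    correction, determines sample thickness and refractive index by
    time-of-flight against an external reference structure (beamsplitter plus
    mirror), fits and ranks Debye, Cole-Cole, Cole-Davidson and
    Havriliak-Negami dielectric relaxation models, builds band-integrated
    transmission raster images to locate inclusions, and screens candidate
    samples against a permittivity reference library. Includes a forward
    waveform simulator with known ground truth so every stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
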