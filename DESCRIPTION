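Package: padfr
Title: Pair Angle Distribution Functions from Fluctuation Scattering Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the pair angle distribution function (PADF) from sets of
    X-ray or electron fluctuation scattering diffraction patterns. Provides the
    full processing chain: detector geometry and polar resampling of diffraction
    images, angular intensity cross-correlation (standard, background and
    difference estimators, with detector-mask correction and odd/even
    convergence splits), conditioning of the correlation volume (Legendre
    sampling weight, q band-pass, theta-zero noise mask), inversion to even-order
    Legendre coefficient matrices B_l(q,q') by regularized singular value
    decomposition on the Ewald sphere, discrete spherical Bessel transforms to
    real space, and assembly of the three-dimensional PADF. A forward kinematic
    diffraction simulator and a brute-force model oracle make the whole chain
    testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite
Config/testthat/edition: 3
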