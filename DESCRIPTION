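Package: depwave
Title: Spectral Analysis of Rectangular Waveforms for Dielectrophoresis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Decides when rectangular (square-wave) excitation increases or
    decreases the net dielectrophoretic (DEP) force on a spherical particle.
    Implements the Clausius-Mossotti dispersion and cross-over frequency for
    homogeneous spheres, Fourier harmonic accounting of ideal square waves
    (line amplitudes, RMS values, spectral energies, Parseval consistency),
    sign-separated per-harmonic DEP force summation, a waveform-choice
    advisor combining the conservative f0 < fco/5 energy rule with an exact
    per-harmonic decomposition, and the trapping failure-rate and
    fluorescence-trace separation-efficiency metrics together with a
    synthetic three-phase trace generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
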