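Package: lfpcoupling
Title: Oscillatory Coupling Analysis of Two-Region Intracranial Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing directed oscillatory coupling between two
    brain regions recorded with intracranial depth electrodes. Implements the
    full analysis chain from raw local field potentials to directional
    connectivity: zero-phase FIR filtering and line-noise regression,
    white-matter re-referencing, Welch power spectra with power-law slope
    fitting and subject-specific low-frequency band selection, an adaptive
    filter-bank Hilbert decomposition, event-locked high-gamma statistics with
    cluster-mass permutation tests, phase-locking values with a two-step
    permutation significance scheme, circular-linear phase-amplitude coupling
    with permutation z-scores and time-lagged profiles, the phase slope index,
    and spectral Granger causality. A synthetic-data module generates
    task-structured two-region recordings with known, recoverable coupling
    parameters (1/f background, condition-dependent cross-frequency coupling
    with conduction lag, evoked high-gamma responses, line noise, and
    electro-oculogram channels with saccades) so every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
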