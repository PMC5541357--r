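Package: saskit
Title: Small-Angle Scattering One-Dimensional Data Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and analysis of one-dimensional small-angle X-ray and
    neutron scattering (SAXS/SANS) curves: reading and writing ASCII scattering
    data, curve arithmetic, averaging, scaling, merging and absolute-scale
    calibration; statistical curve comparison by reduced chi-squared and the
    exact longest-run (correlation map) test; Guinier analysis with automatic
    interval selection; regularized indirect Fourier transformation to the
    pair-distance distribution p(r) with automatic maximum-dimension search and
    sphere-kernel size distributions; Porod invariant, volume-of-correlation
    and sequence-based molecular-weight estimation; Shannon-sampling analysis
    of the useful angular range; analytic form factors of simple geometric
    bodies, Debye evaluation of bead models, mixture and volume-fraction
    decomposition, and singular-value estimation of the number of scattering
    components. Includes a synthetic-data generator for reproducible testing
    of every method against closed-form references.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
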