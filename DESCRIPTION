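Package: saskit
Title: Small-Angle Scattering Data Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing and model-based analysis of one-dimensional
    small-angle X-ray scattering (SAXS) profiles. Provides automatic
    Guinier analysis, curve arithmetic, statistical comparison and
    merging, extrapolation of concentration series to infinite dilution,
    Porod-invariant particle volume and molecular-mass estimation,
    Debye-sum intensity calculation from coordinate and bead models with
    scale plus bounded-constant fitting, non-negative decomposition of
    equilibrium-mixture data into component volume fractions, genetic
    ensemble selection for flexible systems, generation of self-avoiding
    C-alpha random-loop libraries with anchored linker queries, and
    multi-model comparison via the normalized spatial discrepancy with
    Kelley-criterion clustering. Density maps in MRC/CCP4 format can be
    converted to bead models. A synthetic-data module generates analytic
    body form factors, random bead models and noisy concentration series
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
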