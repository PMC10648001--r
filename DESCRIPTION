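Package: mixlib
Title: Curated Mass Spectral Library Generation from Known Chemical Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns data-dependent LC-HRMS/MS runs of known chemical mixtures
    into a curated open mass-spectral library. Provides extracted-ion-
    chromatogram quality control with pass/fail verdicts, fragment sub-formula
    annotation and m/z recalibration, cross-mix disambiguation of isobaric
    compounds by retention-time anchoring, MassBank-format record assembly,
    validation and summarisation (including SPLASH spectral hashes), and
    construction of PubChem deposition tables with Top-5 peaks. A seeded
    synthetic-fixture generator emulates multi-mix designs with Gaussian
    chromatographic peaks, DDA MS2 scans, planted mass-error curves and
    co-isolated isobars so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    ggplot2,
    yaml,
    ini,
    digest,
    pracma,
    mzR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
SystemRequirements: OpenBabel (obabel on the PATH) for SMILES
    standardisation and InChI generation; Python 3 for the bundled
    SPLASH cross-check oracle.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
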