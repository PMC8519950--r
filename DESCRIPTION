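Package: parlock
Title: Photoactivatable-Ribonucleoside Crosslinked RNA-Binding Site
    Identification from Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies RNA-binding sites crosslinked to photoactivatable
    ribonucleosides (4-thiouridine, 6-thioguanosine) at single amino acid
    resolution from centroided MS/MS spectra.  Implements an elemental adduct
    mass model with ribose neutral loss, a scan-duplication database search
    with precursor mass correction, unique-mass-class clustering with site
    localization scoring, target-decoy FDR control, label-free
    quantification, adduct-characterization survey profiles, and a seeded
    synthetic-data generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
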