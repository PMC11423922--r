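Package: dicombids
Title: Heuristic-Driven Conversion of DICOM Studies into BIDS Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts collections of DICOM files (directories, explicit file
    lists, or zip archives) into NIfTI volumes organised as Brain Imaging
    Data Structure (BIDS) datasets. A three-stage workflow (discovery,
    optional manual tuning of proposed filenames, conversion) is driven by
    pluggable naming heuristics, including the ReproIn convention for fully
    automatic conversion of consistently named scanner protocols. Handles
    multi-echo acquisitions and single-band reference volumes, builds RAS
    affines from DICOM slice geometry, writes JSON sidecar metadata,
    populates the standard BIDS dataset files, and can obfuscate subject
    identifiers and visit timestamps while preserving inter-visit
    intervals. A synthetic DICOM study generator with known ground-truth
    geometry supports fully offline testing.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
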