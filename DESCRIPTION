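Package: mosaicdpcr
Title: Digital PCR Quantification of Low-Level GNAS Mosaicism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying low-abundance mosaic GNAS
    variants (c.604C>T and c.605G>A, the McCune-Albright syndrome and fibrous
    dysplasia hotspots) by chip-based digital PCR. Simulates 20,000-partition
    nanowell chips with known ground truth, classifies partitions by FAM
    fluorescence and per-well quality, converts positive-partition counts to
    mutant copies per microlitre by Poisson occupancy correction and to ng/ul
    by the instrument's absolute-quantification formula, builds calibrator
    curves from serial dilutions of heterozygous mutant controls to derive
    positivity cutoffs and the limit of detection, and tabulates detection
    rates across Sanger, allele-specific PCR, COLD-MAMA PCR and digital PCR
    over a multi-tissue patient cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
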