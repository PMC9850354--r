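Package: gipsmix
Title: Identification of Isomeric Glycan Components in Mixtures from
    Multistage Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns the isomeric glycan components of a permethylated,
    sodiated glycan mixture from its MALDI multistage mass spectra
    (MSn). Candidate structures drawn from a local sequence database are
    partitioned into branching patterns, all non-empty candidate groups
    are enumerated, theoretical glycosidic-cleavage spectra are
    simulated for every group, and groups are scored against the
    experimental spectra tree with a tanh-weighted peak-intensity
    similarity penalised by group size. Ties between groups are broken
    by an entropy-based distinguishing-power criterion that recommends
    the most informative fragment ion for the next product-ion scan.
    Includes an mzXML reader/writer, a condensed-notation glycan
    parser, and a synthetic-spectra generator that acts as a virtual
    instrument for closed-loop testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mzR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
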