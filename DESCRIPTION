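Package: tillseq
Title: Pooled TILLING-by-Sequencing Simulation and Mutation Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for screening EMS-mutagenized plant populations by pooled
    target-capture sequencing (TILLING by sequencing). Builds bidimensional
    plate-pooling designs and decodes pool pairs back to candidate wells,
    simulates EMS-mutagenized M2 populations with a transition-biased mutation
    spectrum and Mendelian selfing to M3, simulates pooled sequencing at the
    allele-count level, detects and filters low-frequency pool variants with a
    binomial error-model quality score, demultiplexes retained variants to
    candidate lines and resolves carriers, annotates coding-sequence variants
    at codon level (missense, silent, nonsense), and summarizes mutation
    spectra, effect classes, mutation density per kb screened, and Ks-based
    duplication dating.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
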