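Package: HetErrEval
Title: Haplotype-Aware Evaluation of NGS Error Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates how read error-correction software treats
    heterozygous sequencing data. Simulates a synthetic diploid genome with
    single-nucleotide heterozygous sites at a controlled rate, generates
    truth-tracked single-end reads with substitution errors, applies
    pluggable correctors (reference controls, a simplified k-mer-spectrum
    corrector, or externally corrected FASTQ), and classifies every
    correction event with respect to haplotype identity: corrected
    correctly, not corrected, corrected to the wrong haplotype, corrected to
    neither haplotype, or removed by trimming. Reports base-level outcome
    rates, introduced-error rates at non-error heterozygous positions, and
    read-level chimeric-read statistics, over a factorial sweep of
    heterozygosity and error rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
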