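#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet BStringSet readDNAStringSet
#'   writeXStringSet reverseComplement
#' @importFrom IRanges IRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats runif rbinom
#' @importFrom utils read.delim write.table
#' @useDynLib HetErrEval, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

VALID_BASES <- c("A", "C", "G", "T")

OUTCOMES <- c(
    corrected_correctly = "corrected_correctly",
    not_corrected       = "not_corrected",
    wrong_haplotype     = "wrong_haplotype",
    neither_haplotype   = "neither_haplotype",
    miscorrected        = "miscorrected",
    unchanged           = "unchanged",
    trimmed             = "trimmed"
)

#' HaplotypePair: a synthetic diploid genome
#'
#' Two equal-length haplotype sequences that differ only by single-nucleotide
#' variants at a controlled set of heterozygous sites. Haplotype A is always
#' the unmodified source sequence; haplotype B carries the injected variants.
#'
#' @slot name Character label for the genome.
#' @slot hapA,hapB \link[Biostrings]{DNAString} haplotype sequences of equal
#'   length.
#' @slot hetSites \code{data.frame} with columns \code{pos} (0-based),
#'   \code{baseA}, \code{baseB}; rows ordered by strictly increasing
#'   \code{pos}.
#' @slot hetRate Numeric heterozygosity rate in \code{[0, 0.10]} used to
#'   generate the sites.
#'
#' @seealso [introduceHeterozygosity()] which constructs objects of this
#'   class, and [simulateReads()] which consumes them.
#' @export
setClass("HaplotypePair",
    representation(
        name     = "character",
        hapA     = "DNAString",
        hapB     = "DNAString",
        hetSites = "data.frame",
        hetRate  = "numeric"
    )
)

setValidity("HaplotypePair", function(object) {
    msg <- character()
    a <- as.character(object@hapA)
    b <- as.character(object@hapB)
    hs <- object@hetSites
    if (nchar(a) != nchar(b))
        msg <- c(msg, "hapA and hapB must have equal length")
    if (!all(c("pos", "baseA", "baseB") %in% names(hs)))
        msg <- c(msg, "hetSites needs columns pos, baseA, baseB")
    if (length(object@hetRate) != 1 ||
        object@hetRate < 0 || object@hetRate > 0.10)
        msg <- c(msg, "hetRate must be a single value in [0, 0.10]")
    if (length(msg)) return(msg)
    if (nrow(hs)) {
        if (is.unsorted(hs$pos, strictly = TRUE))
            msg <- c(msg, "het site positions must be strictly increasing")
        if (any(hs$pos < 0) || any(hs$pos >= nchar(a)))
            msg <- c(msg, "het site positions out of range")
        if (any(hs$baseA == hs$baseB))
            msg <- c(msg, "het sites must differ between haplotypes")
        p1 <- hs$pos + 1L
        if (!all(substring(a, p1, p1) == hs$baseA))
            msg <- c(msg, "hapA disagrees with hetSites baseA")
        if (!all(substring(b, p1, p1) == hs$baseB))
            msg <- c(msg, "hapB disagrees with hetSites baseB")
    }
    # all remaining positions identical
    a2 <- a
    if (nrow(hs)) {
        ch <- strsplit(a2, "")[[1]]
        ch[hs$pos + 1L] <- hs$baseB
        a2 <- paste(ch, collapse = "")
    }
    if (a2 != b)
        msg <- c(msg, "haplotypes differ outside the recorded het sites")
    if (length(msg)) msg else TRUE
})

#' SimulatedReadset: reads plus a complete truth ledger
#'
#' Fixed-length single-end reads simulated from a [HaplotypePair-class],
#' with per-read provenance (source haplotype, genome start, strand) and the
#' full list of injected substitution errors, so that every downstream
#' correction event can be classified exactly.
#'
#' Error offsets are 0-based positions within the read \emph{as written}
#' (i.e. after reverse-complementing minus-strand reads); \code{true_base}
#' is in the same read orientation.
#'
#' @slot reads Named \link[Biostrings]{DNAStringSet} of read sequences.
#' @slot truth \code{data.frame}, one row per read: \code{read_id},
#'   \code{haplotype} ("A"/"B"), \code{start} (0-based), \code{strand}
#'   ("+"/"-"), \code{length}.
#' @slot errors \code{data.frame}, one row per injected error:
#'   \code{read_id}, \code{offset} (0-based, read orientation),
#'   \code{true_base}.
#' @slot params List of the simulation parameters
#'   (\code{read_length}, \code{coverage}, \code{error_rate}, \code{seed},
#'   \code{het_rate}, \code{genome_length}).
#'
#' @seealso [simulateReads()], [verifyReadset()], [splitByHaplotype()]
#' @export
setClass("SimulatedReadset",
    representation(
        reads  = "DNAStringSet",
        truth  = "data.frame",
        errors = "data.frame",
        params = "list"
    )
)

setValidity("SimulatedReadset", function(object) {
    msg <- character()
    tr <- object@truth
    if (!all(c("read_id", "haplotype", "start", "strand", "length") %in%
             names(tr)))
        msg <- c(msg, "truth needs read_id, haplotype, start, strand, length")
    if (!all(c("read_id", "offset", "true_base") %in% names(object@errors)))
        msg <- c(msg, "errors needs read_id, offset, true_base")
    if (length(msg)) return(msg)
    ids <- names(object@reads)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "reads must be uniquely named by read_id")
    else if (!identical(sort(ids), sort(tr$read_id)))
        msg <- c(msg, "reads and truth must contain the same read_ids")
    if (!all(object@errors$read_id %in% tr$read_id))
        msg <- c(msg, "errors reference unknown read_ids")
    if (!all(tr$haplotype %in% c("A", "B")))
        msg <- c(msg, "haplotype must be 'A' or 'B'")
    if (!all(tr$strand %in% c("+", "-")))
        msg <- c(msg, "strand must be '+' or '-'")
    if (length(msg)) msg else TRUE
})

#' CorrectedReadset: a corrector's output matched to the original reads
#'
#' Holds the corrected sequence for every surviving read, keyed by read id.
#' Reads the corrector removed outright are simply absent; a corrected
#' sequence may be shorter than the original (end trimming) but never
#' longer.
#'
#' @slot records Named \link[Biostrings]{DNAStringSet} of corrected
#'   sequences; names are read ids present in the original readset.
#' @slot corrector Character label (corrector name).
#' @slot params List of corrector parameters, for provenance.
#'
#' @seealso [oracleCorrect()], [kspectrumCorrect()],
#'   [loadExternalCorrected()], [evaluateCorrections()]
#' @export
setClass("CorrectedReadset",
    representation(
        records   = "DNAStringSet",
        corrector = "character",
        params    = "list"
    )
)

setValidity("CorrectedReadset", function(object) {
    ids <- names(object@records)
    if (length(object@records) &&
        (is.null(ids) || anyDuplicated(ids)))
        return("records must be uniquely named by read_id")
    TRUE
})

#' EvaluationReport: base-level correction outcome counts and rates
#'
#' Counts of every classified base by stratum, where a stratum is the pair
#' (zygosity of the genome position, error status of the base as written).
#' Rates are derived on demand by [rateCorrected()], [rateIntroduced()] and
#' [rateOccurrence()].
#'
#' @slot counts \code{data.frame} with columns \code{zygosity}
#'   ("het"/"hom"), \code{truth_status} ("error"/"non_error"),
#'   \code{outcome}, \code{count}.
#' @slot meta List of evaluation metadata (het_rate, error_rate, corrector,
#'   mode, n_reads).
#'
#' @seealso [evaluateCorrections()]
#' @export
setClass("EvaluationReport",
    representation(counts = "data.frame", meta = "list"))

setValidity("EvaluationReport", function(object) {
    cn <- c("zygosity", "truth_status", "outcome", "count")
    if (!all(cn %in% names(object@counts)))
        return("counts needs zygosity, truth_status, outcome, count")
    if (any(object@counts$count < 0))
        return("counts must be non-negative")
    TRUE
})

#' ChimeraReport: read-level marker and chimera statistics
#'
#' A chimeric read carries more than one heterozygous marker and represents
#' both haplotypes among them — impossible for a faithfully corrected read
#' from a single haplotype.
#'
#' @slot nReadsTotal Total reads in the evaluated readset (removed reads
#'   included).
#' @slot nMultimarker Reads with more than one surviving heterozygous
#'   marker.
#' @slot nChimeric Multimarker reads whose markers represent both
#'   haplotypes.
#' @slot meta List of metadata.
#'
#' @seealso [chimeraReport()], [isChimeric()]
#' @export
setClass("ChimeraReport",
    representation(
        nReadsTotal  = "integer",
        nMultimarker = "integer",
        nChimeric    = "integer",
        meta         = "list"
    )
)

setValidity("ChimeraReport", function(object) {
    if (object@nChimeric > object@nMultimarker ||
        object@nMultimarker > object@nReadsTotal)
        return("need nChimeric <= nMultimarker <= nReadsTotal")
    TRUE
})

#' SweepConfig: the factorial experiment over heterozygosity and error rate
#'
#' Describes a full sweep: the genome source, the heterozygosity and error
#' rate grids, read simulation parameters, dataset modes and correctors.
#' The defaults reproduce the study design: 50 heterozygosity levels times
#' 4 error rates = 200 datasets of 75 bp single-end reads at 40x combined
#' coverage.
#'
#' @slot genomeLength Length of the random reference to simulate (ignored
#'   when \code{fastaPath} is set).
#' @slot fastaPath Optional path to a FASTA file supplying the reference
#'   (first record used); \code{NA} for a random reference.
#' @slot hetRates Numeric vector of heterozygosity rates.
#' @slot errorRates Numeric vector of per-base substitution error rates.
#' @slot readLength,coverage Read simulation parameters.
#' @slot modes Character subset of \code{c("heterozygous", "homozygous")}.
#' @slot correctors Named list: corrector name -> list of parameters.
#' @slot masterSeed Integer master seed; per-configuration seeds are derived
#'   deterministically from it.
#' @slot outputDir Directory for per-configuration TSV reports, or \code{NA}
#'   to keep results in memory only.
#'
#' @seealso [sweepConfig()], [enumerateConfigs()], [runSweep()]
#' @export
setClass("SweepConfig",
    representation(
        genomeLength = "integer",
        fastaPath    = "character",
        hetRates     = "numeric",
        errorRates   = "numeric",
        readLength   = "integer",
        coverage     = "numeric",
        modes        = "character",
        correctors   = "list",
        masterSeed   = "integer",
        outputDir    = "character"
    )
)

setValidity("SweepConfig", function(object) {
    msg <- character()
    if (length(object@hetRates) == 0 || length(object@errorRates) == 0)
        msg <- c(msg, "hetRates and errorRates must be non-empty")
    if (any(object@hetRates < 0) || any(object@hetRates > 0.10))
        msg <- c(msg, "hetRates must lie in [0, 0.10]")
    if (any(object@errorRates < 0) || any(object@errorRates >= 1))
        msg <- c(msg, "errorRates must lie in [0, 1)")
    if (!all(object@modes %in% c("heterozygous", "homozygous")))
        msg <- c(msg, "modes must be 'heterozygous' and/or 'homozygous'")
    if (length(object@correctors) == 0 ||
        is.null(names(object@correctors)))
        msg <- c(msg, "correctors must be a named list")
    if (length(msg)) msg else TRUE
})
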