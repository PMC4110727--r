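#' Generate a random reference sequence
#'
#' Uniform i.i.d. A/C/G/T string, used as the source haplotype when no real
#' reference FASTA is supplied.
#'
#' @param length Positive integer, sequence length in bp.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A \link[Biostrings]{DNAString} of the requested length.
#' @examples
#' randomReference(50, seed = 1)
#' @export
randomReference <- function(length, seed = NULL) {
    if (length(length) != 1 || is.na(length) || length < 1)
        stop("length must be a single positive integer")
    s <- with_seed(seed,
        paste(sample(VALID_BASES, length, replace = TRUE), collapse = ""))
    Biostrings::DNAString(s)
}

#' The 50-level heterozygosity grid
#'
#' Heterozygosity rates from 0.2\% to 10\% in 0.2\% steps — the 50 levels of
#' the factorial study design.
#'
#' @return Numeric vector of length 50: \code{0.002, 0.004, ..., 0.100}.
#' @examples
#' length(hetGrid())
#' @export
hetGrid <- function() {
    round(seq_len(50) * 0.002, 3)
}

#' Construct a synthetic diploid genome
#'
#' Duplicates a source sequence and injects single-nucleotide heterozygous
#' sites into the copy at a controlled rate. The original sequence becomes
#' haplotype A; the copy with exactly \code{round(hetRate * length)}
#' substitutions (positions sampled uniformly without replacement, the
#' substituted base uniform among the three alternatives) becomes
#' haplotype B. \code{round()} uses round-half-even.
#'
#' @param seq Source sequence: a \link[Biostrings]{DNAString} or a single
#'   character string over \{A,C,G,T\}. Ambiguity codes are rejected.
#' @param hetRate Heterozygosity rate, a fraction in \code{[0, 0.10]}.
#' @param seed Integer seed; the pair is deterministic given the seed.
#' @param name Label for the genome.
#' @return A [HaplotypePair-class] object.
#' @examples
#' pair <- introduceHeterozygosity(randomReference(1000, 1), 0.02, seed = 7)
#' nrow(hetSites(pair))   # exactly round(0.02 * 1000) = 20
#' @export
introduceHeterozygosity <- function(seq, hetRate, seed = NULL,
                                    name = "synthetic_diploid") {
    s <- toupper(as.character(seq))
    if (length(s) != 1 || nchar(s) == 0)
        stop("seq must be a single non-empty sequence")
    assert_dna(s, "seq")
    if (length(hetRate) != 1 || is.na(hetRate) ||
        hetRate < 0 || hetRate > 0.10)
        stop("hetRate must be a single fraction in [0, 0.10]")
    L <- nchar(s)
    nSites <- as.integer(round(hetRate * L))
    hs <- with_seed(seed, {
        if (nSites > 0) {
            pos <- sort(sample.int(L, nSites))          # 1-based here
            baseA <- substring(s, pos, pos)
            # uniform among the 3 alternatives
            alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                          nrow = 4, byrow = TRUE,
                          dimnames = list(VALID_BASES, NULL))
            pick <- sample.int(3, nSites, replace = TRUE)
            baseB <- alt[cbind(match(baseA, VALID_BASES), pick)]
            data.frame(pos = pos - 1L, baseA = baseA, baseB = baseB,
                       stringsAsFactors = FALSE)
        } else {
            data.frame(pos = integer(), baseA = character(),
                       baseB = character(), stringsAsFactors = FALSE)
        }
    })
    b <- s
    if (nrow(hs)) {
        ch <- strsplit(s, "")[[1]]
        ch[hs$pos + 1L] <- hs$baseB
        b <- paste(ch, collapse = "")
    }
    new("HaplotypePair", name = name,
        hapA = Biostrings::DNAString(s), hapB = Biostrings::DNAString(b),
        hetSites = hs, hetRate = hetRate)
}

#' @describeIn HaplotypePair-class Haplotype A (the unmodified source).
#' @param x,object A \code{HaplotypePair}.
#' @export
hapA <- function(x) x@hapA

#' @describeIn HaplotypePair-class Haplotype B (carrying the variants).
#' @export
hapB <- function(x) x@hapB

#' @describeIn HaplotypePair-class Table of heterozygous sites
#'   (\code{pos} 0-based, \code{baseA}, \code{baseB}).
#' @export
hetSites <- function(x) x@hetSites

#' @describeIn HaplotypePair-class The heterozygosity rate used.
#' @export
hetRate <- function(x) x@hetRate

#' @describeIn HaplotypePair-class Haploid genome length in bp.
#' @export
genomeLength <- function(x) length(x@hapA)

setMethod("show", "HaplotypePair", function(object) {
    cat("HaplotypePair '", object@name, "'\n", sep = "")
    cat("  haploid length: ", genomeLength(object), " bp\n", sep = "")
    cat("  het sites: ", nrow(object@hetSites),
        sprintf(" (rate %.4g)\n", object@hetRate), sep = "")
})

#' Write / read a HaplotypePair
#'
#' The two haplotypes go to a 2-record FASTA (\code{<name>_hapA},
#' \code{<name>_hapB}); the heterozygous sites to a TSV with header
#' \code{pos  baseA  baseB} (\code{pos} 0-based).
#'
#' @param pair A [HaplotypePair-class].
#' @param fastaPath,sitesPath Output (or input) file paths.
#' @param hetRate Rate to record on read-back (stored only in the object,
#'   not in the files); defaults to the fraction implied by the site count.
#' @return \code{writeHaplotypePair} returns the paths invisibly;
#'   \code{readHaplotypePair} returns a [HaplotypePair-class].
#' @export
writeHaplotypePair <- function(pair, fastaPath, sitesPath) {
    seqs <- Biostrings::DNAStringSet(c(as.character(pair@hapA),
                                       as.character(pair@hapB)))
    names(seqs) <- paste0(pair@name, c("_hapA", "_hapB"))
    Biostrings::writeXStringSet(seqs, fastaPath)
    write.table(pair@hetSites, sitesPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(c(fasta = fastaPath, sites = sitesPath))
}

#' @rdname writeHaplotypePair
#' @export
readHaplotypePair <- function(fastaPath, sitesPath, hetRate = NULL) {
    seqs <- Biostrings::readDNAStringSet(fastaPath)
    if (length(seqs) != 2)
        stop("expected a 2-record FASTA (hapA, hapB)")
    hs <- read.delim(sitesPath, stringsAsFactors = FALSE,
                     colClasses = c("integer", "character", "character"))
    name <- sub("_hapA$", "", names(seqs)[1])
    if (is.null(hetRate)) hetRate <- nrow(hs) / Biostrings::width(seqs)[1]
    new("HaplotypePair", name = name,
        hapA = Biostrings::DNAString(as.character(seqs[[1]])),
        hapB = Biostrings::DNAString(as.character(seqs[[2]])),
        hetSites = hs, hetRate = hetRate)
}
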