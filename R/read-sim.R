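#' Inject substitution errors into read sequences
#'
#' Each base is independently substituted with probability \code{errorRate}
#' by a base drawn uniformly from the three alternatives. Uses the current
#' RNG state (seed it with \code{set.seed()} for reproducibility);
#' [simulateReads()] calls this internally under its own seed.
#'
#' @param seqs Character vector of read sequences (A/C/G/T).
#' @param errorRate Per-base substitution probability in \code{[0, 1)}.
#' @return A list with \code{seqs} (mutated sequences, names preserved) and
#'   \code{errors}, a \code{data.frame} with \code{read} (index into
#'   \code{seqs}), \code{offset} (0-based position within the read) and
#'   \code{true_base} (the pre-error base). At every recorded error the
#'   mutated base differs from \code{true_base}.
#' @export
injectErrors <- function(seqs, errorRate) {
    if (errorRate < 0 || errorRate >= 1)
        stop("errorRate must lie in [0, 1)")
    lens <- nchar(seqs)
    total <- sum(lens)
    empty <- data.frame(read = integer(), offset = integer(),
                        true_base = character(), stringsAsFactors = FALSE)
    if (total == 0 || errorRate == 0)
        return(list(seqs = seqs, errors = empty))
    hit <- which(runif(total) < errorRate)
    if (!length(hit)) return(list(seqs = seqs, errors = empty))
    bounds <- cumsum(c(0, lens))
    read <- findInterval(hit - 1L, bounds)          # 1..n
    offset <- (hit - 1L) - bounds[read]
    big <- paste(seqs, collapse = "")
    old <- substring(big, hit, hit)
    alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                  nrow = 4, byrow = TRUE)
    newb <- alt[cbind(match(old, VALID_BASES),
                      sample.int(3, length(hit), replace = TRUE))]
    mutated <- substitute_chars(seqs, read, offset + 1L, newb)
    list(seqs = mutated,
         errors = data.frame(read = as.integer(read),
                             offset = as.integer(offset),
                             true_base = old, stringsAsFactors = FALSE))
}

#' Simulate truth-tracked single-end reads from a diploid genome
#'
#' Emulates Illumina-like single-end sequencing of a synthetic diploid:
#' \code{N = round(coverage * L / readLength)} reads (L the haploid length,
#' so \code{coverage} is the \emph{combined} diploid coverage, about half
#' per haplotype), each drawn from haplotype A or B with probability 1/2,
#' start uniform, strand uniform, with i.i.d. substitution errors at
#' \code{errorRate} per base. All error offsets are recorded in read
#' orientation, so the truth ledger fully determines the source bases.
#' Quality strings are constant 'I' (Q40) — the evaluation never uses them.
#'
#' @param pair A [HaplotypePair-class].
#' @param readLength Read length in bp (default 75).
#' @param coverage Combined fold-coverage over the haploid length
#'   (default 40).
#' @param errorRate Per-base substitution error probability (the study's
#'   four levels were about 0.037, 0.046, 0.058 and 0.073).
#' @param seed Integer seed; the readset is deterministic given the seed.
#' @return A [SimulatedReadset-class].
#' @examples
#' pair <- introduceHeterozygosity(randomReference(2000, 1), 0.02, seed = 2)
#' rs <- simulateReads(pair, readLength = 75, coverage = 10,
#'                     errorRate = 0.037, seed = 3)
#' verifyReadset(rs, pair)
#' @export
simulateReads <- function(pair, readLength = 75L, coverage = 40,
                          errorRate = 0.037, seed = NULL) {
    stopifnot(is(pair, "HaplotypePair"))
    L <- genomeLength(pair)
    readLength <- as.integer(readLength)
    if (readLength > L) stop("readLength exceeds genome length")
    if (coverage <= 0) stop("coverage must be positive")
    if (errorRate < 0 || errorRate >= 1) stop("errorRate must lie in [0, 1)")
    N <- as.integer(round(coverage * L / readLength))
    hapStr <- c(A = as.character(pair@hapA), B = as.character(pair@hapB))

    res <- with_seed(seed, {
        hap <- sample(c("A", "B"), N, replace = TRUE)
        start <- sample.int(L - readLength + 1L, N, replace = TRUE) - 1L
        strand <- sample(c("+", "-"), N, replace = TRUE)
        seqs <- substring(hapStr[hap], start + 1L, start + readLength)
        neg <- strand == "-"
        if (any(neg)) seqs[neg] <- revcomp_chr(seqs[neg])
        inj <- injectErrors(seqs, errorRate)
        list(hap = hap, start = start, strand = strand, inj = inj)
    })

    ids <- sprintf("read%07d", seq_len(N))
    reads <- Biostrings::DNAStringSet(res$inj$seqs)
    names(reads) <- ids
    truth <- data.frame(read_id = ids, haplotype = res$hap,
                        start = res$start, strand = res$strand,
                        length = rep(readLength, N),
                        stringsAsFactors = FALSE)
    err <- res$inj$errors
    errors <- data.frame(read_id = ids[err$read], offset = err$offset,
                         true_base = err$true_base, stringsAsFactors = FALSE)
    new("SimulatedReadset", reads = reads, truth = truth, errors = errors,
        params = list(read_length = readLength, coverage = coverage,
                      error_rate = errorRate, seed = seed,
                      het_rate = hetRate(pair), genome_length = L))
}

#' @describeIn SimulatedReadset-class The read sequences as a named
#'   \link[Biostrings]{DNAStringSet}.
#' @param x,object A \code{SimulatedReadset}.
#' @export
reads <- function(x) x@reads

#' @describeIn SimulatedReadset-class Per-read truth table (one row per
#'   read).
#' @export
truthTable <- function(x) x@truth

#' @describeIn SimulatedReadset-class Injected-error table (one row per
#'   error).
#' @export
errorTable <- function(x) x@errors

#' @describeIn SimulatedReadset-class Simulation parameters as a list.
#' @export
simParams <- function(x) x@params

setMethod("show", "SimulatedReadset", function(object) {
    p <- object@params
    cat("SimulatedReadset: ", length(object@reads), " reads x ",
        p$read_length, " bp\n", sep = "")
    cat(sprintf("  coverage %.4g, error rate %.4g, %d injected errors\n",
                p$coverage, p$error_rate, nrow(object@errors)))
})

setMethod("length", "SimulatedReadset", function(x) length(x@reads))

#' Split a readset by source haplotype
#'
#' Partitions a simulated readset into its haplotype-A and haplotype-B
#' reads using the truth ledger — the study's "homozygous dataset"
#' construction, where each half is corrected independently.
#'
#' @param rs A [SimulatedReadset-class].
#' @return A list with elements \code{A} and \code{B}, each a
#'   [SimulatedReadset-class]; the two partition the input.
#' @export
splitByHaplotype <- function(rs) {
    stopifnot(is(rs, "SimulatedReadset"))
    out <- lapply(c(A = "A", B = "B"), function(h) {
        keep <- rs@truth$haplotype == h
        ids <- rs@truth$read_id[keep]
        new("SimulatedReadset",
            reads = rs@reads[ids],
            truth = rs@truth[keep, , drop = FALSE],
            errors = rs@errors[rs@errors$read_id %in% ids, , drop = FALSE],
            params = rs@params)
    })
    out
}

#' Verify a readset against its truth ledger
#'
#' Checks every invariant of the truth ledger against the haplotype pair:
#' starts in range, error offsets unique and in range, written base differs
#' from the recorded true base, and — the reconstruction oracle — undoing
#' all errors and reverse-complementing minus-strand reads reproduces the
#' source haplotype segment exactly.
#'
#' @param rs A [SimulatedReadset-class].
#' @param pair The [HaplotypePair-class] it was simulated from.
#' @return \code{TRUE} if every invariant holds, else \code{FALSE}.
#' @export
verifyReadset <- function(rs, pair) {
    tr <- rs@truth
    L <- genomeLength(pair)
    if (any(tr$start < 0) || any(tr$start > L - tr$length)) return(FALSE)
    err <- rs@errors
    if (nrow(err)) {
        ri <- match(err$read_id, tr$read_id)
        if (anyNA(ri)) return(FALSE)
        if (any(err$offset < 0) || any(err$offset >= tr$length[ri]))
            return(FALSE)
        if (anyDuplicated(paste(err$read_id, err$offset))) return(FALSE)
        seqs <- as.character(rs@reads)[match(err$read_id, names(rs@reads))]
        written <- substring(seqs, err$offset + 1L, err$offset + 1L)
        if (any(written == err$true_base)) return(FALSE)
    }
    # reconstruction
    seqs <- as.character(rs@reads)
    names(seqs) <- names(rs@reads)
    if (nrow(err)) {
        idx <- match(err$read_id, names(seqs))
        seqs <- substitute_chars(seqs, idx, err$offset + 1L, err$true_base)
    }
    seqs <- seqs[tr$read_id]
    neg <- tr$strand == "-"
    if (any(neg)) seqs[neg] <- revcomp_chr(seqs[neg])
    hapStr <- c(A = as.character(pair@hapA), B = as.character(pair@hapB))
    expected <- substring(hapStr[tr$haplotype], tr$start + 1L,
                          tr$start + tr$length)
    all(seqs == expected)
}

#' Write / read a simulated readset
#'
#' Reads go to a standard 4-line FASTQ (constant quality 'I'); the truth
#' ledger to a TSV with header
#' \code{read_id haplotype start strand length errors}, where \code{errors}
#' is a semicolon-joined list of \code{offset:true_base} entries or
#' \code{.} when the read has none. Coordinates are 0-based, half-open.
#'
#' @param rs A [SimulatedReadset-class].
#' @param fastqPath,truthPath File paths.
#' @param params Simulation parameter list to attach on read-back.
#' @return \code{writeReadset} returns the paths invisibly;
#'   \code{readReadset} returns a [SimulatedReadset-class].
#' @export
writeReadset <- function(rs, fastqPath, truthPath) {
    qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(rs@reads)))
    Biostrings::writeXStringSet(rs@reads, fastqPath, format = "fastq",
                                qualities = qual)
    err <- rs@errors
    errStr <- rep(".", nrow(rs@truth))
    if (nrow(err)) {
        joined <- vapply(split(paste0(err$offset, ":", err$true_base),
                               factor(err$read_id,
                                      levels = rs@truth$read_id)),
                         paste, character(1), collapse = ";")
        errStr[joined != ""] <- joined[joined != ""]
    }
    tab <- cbind(rs@truth, errors = errStr)
    write.table(tab, truthPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(fastq = fastqPath, truth = truthPath))
}

#' @rdname writeReadset
#' @export
readReadset <- function(fastqPath, truthPath, params = list()) {
    seqs <- Biostrings::readDNAStringSet(fastqPath, format = "fastq")
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    tab <- read.delim(truthPath, stringsAsFactors = FALSE,
                      colClasses = c("character", "character", "integer",
                                     "character", "integer", "character"))
    has <- tab$errors != "."
    errors <- data.frame(read_id = character(), offset = integer(),
                         true_base = character(), stringsAsFactors = FALSE)
    if (any(has)) {
        pieces <- strsplit(tab$errors[has], ";", fixed = TRUE)
        n <- lengths(pieces)
        flat <- unlist(pieces)
        off <- as.integer(sub(":.*$", "", flat))
        tb <- sub("^.*:", "", flat)
        errors <- data.frame(read_id = rep(tab$read_id[has], n),
                             offset = off, true_base = tb,
                             stringsAsFactors = FALSE)
    }
    new("SimulatedReadset", reads = seqs,
        truth = tab[, c("read_id", "haplotype", "start", "strand", "length")],
        errors = errors, params = params)
}
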