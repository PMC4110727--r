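new_corrected <- function(ids, seqs, corrector, params = list()) {
    recs <- Biostrings::DNAStringSet(seqs)
    names(recs) <- ids
    new("CorrectedReadset", records = recs, corrector = corrector,
        params = params)
}

#' @describeIn CorrectedReadset-class Named
#'   \link[Biostrings]{DNAStringSet} of corrected sequences (removed reads
#'   absent).
#' @param x,object A \code{CorrectedReadset}.
#' @export
records <- function(x) x@records

#' @describeIn CorrectedReadset-class Corrector label.
#' @export
correctorLabel <- function(x) x@corrector

#' @describeIn CorrectedReadset-class Ids of reads the corrector removed,
#'   relative to the original readset.
#' @param rs The original [SimulatedReadset-class].
#' @export
removedIds <- function(x, rs) setdiff(truthTable(rs)$read_id,
                                      names(x@records))

setMethod("show", "CorrectedReadset", function(object) {
    cat("CorrectedReadset from '", object@corrector, "': ",
        length(object@records), " surviving reads\n", sep = "")
})

#' Reference correctors for calibrating the evaluator
#'
#' Deterministic correctors with known ground-truth behaviour, used as
#' positive, negative and adversarial controls for the evaluation
#' machinery:
#' \describe{
#'   \item{\code{oracleCorrect}}{restores every injected error to its true
#'     base and touches nothing else — the perfect corrector. Downstream,
#'     every error base is corrected correctly and no error is introduced.}
#'   \item{\code{identityCorrect}}{returns the reads unchanged — the null
#'     corrector. Downstream, every error base is "not corrected".}
#'   \item{\code{trimCorrect}}{removes the first \code{trimStart} and last
#'     \code{trimEnd} bases of every read, substituting nothing; a read
#'     whose length would reach zero or below is removed entirely.}
#'   \item{\code{flipMarkersCorrect}}{flips each non-error base overlapping
#'     a heterozygous site to the other haplotype's base independently with
#'     probability \code{flipProb} (error bases untouched) — an adversarial
#'     control that manufactures wrong-haplotype corrections and chimeric
#'     reads at a known rate.}
#' }
#'
#' @param rs A [SimulatedReadset-class].
#' @param pair The [HaplotypePair-class] the readset came from.
#' @param flipProb Per-marker flip probability in \code{[0, 1]}.
#' @param seed Integer seed for the flips.
#' @param trimStart,trimEnd Number of bases to remove from each end.
#' @return A [CorrectedReadset-class].
#' @name control-correctors
NULL

#' @rdname control-correctors
#' @export
oracleCorrect <- function(rs) {
    stopifnot(is(rs, "SimulatedReadset"))
    seqs <- as.character(rs@reads)
    names(seqs) <- names(rs@reads)
    err <- rs@errors
    if (nrow(err)) {
        idx <- match(err$read_id, names(seqs))
        seqs <- substitute_chars(seqs, idx, err$offset + 1L, err$true_base)
    }
    new_corrected(names(seqs), unname(seqs), "oracle")
}

#' @rdname control-correctors
#' @export
identityCorrect <- function(rs) {
    stopifnot(is(rs, "SimulatedReadset"))
    new_corrected(names(rs@reads), as.character(rs@reads), "identity")
}

#' @rdname control-correctors
#' @export
trimCorrect <- function(rs, trimStart, trimEnd) {
    stopifnot(is(rs, "SimulatedReadset"), trimStart >= 0, trimEnd >= 0)
    seqs <- as.character(rs@reads)
    lens <- nchar(seqs)
    keep <- trimStart + trimEnd < lens
    out <- substring(seqs[keep], trimStart + 1L, lens[keep] - trimEnd)
    new_corrected(names(rs@reads)[keep], out, "trim",
                  list(trim_start = trimStart, trim_end = trimEnd))
}

#' @rdname control-correctors
#' @export
flipMarkersCorrect <- function(rs, pair, flipProb, seed = NULL) {
    stopifnot(is(rs, "SimulatedReadset"), is(pair, "HaplotypePair"),
              flipProb >= 0, flipProb <= 1)
    tr <- rs@truth
    seqs <- as.character(rs@reads)
    names(seqs) <- names(rs@reads)
    hs <- hetSites(pair)
    if (nrow(hs) && flipProb > 0) {
        ov <- IRanges::findOverlaps(
            IRanges::IRanges(hs$pos + 1L, width = 1L),
            IRanges::IRanges(tr$start + 1L, width = tr$length))
        si <- S4Vectors::queryHits(ov)
        ri <- S4Vectors::subjectHits(ov)
        gpos <- hs$pos[si]
        neg <- tr$strand[ri] == "-"
        off <- ifelse(neg, tr$start[ri] + tr$length[ri] - 1L - gpos,
                      gpos - tr$start[ri])
        # skip error positions
        err <- rs@errors
        isErr <- if (nrow(err))
            paste(tr$read_id[ri], off) %in% paste(err$read_id, err$offset)
        else rep(FALSE, length(ri))
        keep <- !isErr
        ri <- ri[keep]; off <- off[keep]; si <- si[keep]; neg <- neg[keep]
        if (length(ri)) {
            # flip decisions are drawn per read (markers in genome order)
            # from a seed derived from (seed, read_id), so correcting the
            # pooled readset and correcting the haplotype halves commute
            ord <- order(ri, hs$pos[si])
            ri <- ri[ord]; off <- off[ord]; si <- si[ord]; neg <- neg[ord]
            ids <- tr$read_id[ri]
            grp <- split(seq_along(ri), factor(ids, levels = unique(ids)))
            u <- unlist(lapply(grp, function(ix)
                with_seed(derive_seed(seed, ids[ix[1]]),
                          runif(length(ix)))), use.names = FALSE)
            flip <- u < flipProb
            ri <- ri[flip]; off <- off[flip]; si <- si[flip]; neg <- neg[flip]
        }
        if (length(ri)) {
            # other haplotype's base, in read orientation
            other <- ifelse(tr$haplotype[ri] == "A",
                            hs$baseB[si], hs$baseA[si])
            other[neg] <- complement_base(other[neg])
            idx <- match(tr$read_id[ri], names(seqs))
            seqs <- substitute_chars(seqs, idx, off + 1L, other)
        }
    }
    new_corrected(names(seqs), unname(seqs), "flip_markers",
                  list(flip_prob = flipProb, seed = seed))
}

#' Simplified k-spectrum error correction
#'
#' A deliberately minimal corrector of the k-mer-spectrum family: count all
#' k-mers of the readset canonically (each k-mer pooled with its reverse
#' complement), call a k-mer \emph{trusted} when its count reaches
#' \code{trustThreshold}, and for each read containing untrusted k-mers try
#' every single-base substitution at positions covered by an untrusted
#' k-mer. The substitution that maximises the number of trusted k-mers in
#' the read is applied only if it makes \emph{all} of the read's k-mers
#' trusted; otherwise the read is left unchanged (conservative). At most
#' one substitution per read per pass, up to \code{passes} passes; the
#' census is computed once from the input readset and held fixed. Ties
#' among equally good substitutions are broken by smallest (position,
#' base). No quality model, no likelihood ranking and no trimming: the
#' corrector exists to reproduce the phenomenon class under study —
#' genuine heterozygous sites being indistinguishable from errors in a
#' pooled k-mer census.
#'
#' @param rs A [SimulatedReadset-class].
#' @param k K-mer length, \code{1 <= k <= 31} and below the read length.
#' @param trustThreshold Minimum census count for a trusted k-mer.
#' @param passes Maximum correction passes (default 2).
#' @return A [CorrectedReadset-class]; sequences never lengthen and stay
#'   within \{A,C,G,T\}.
#' @export
kspectrumCorrect <- function(rs, k = 15L, trustThreshold = 2L, passes = 2L) {
    stopifnot(is(rs, "SimulatedReadset"))
    k <- as.integer(k)
    if (k < 1 || k > 31) stop("k must lie in [1, 31]")
    if (k >= rs@params$read_length)
        stop("k must be smaller than the read length")
    if (trustThreshold < 1) stop("trustThreshold must be >= 1")
    seqs <- as.character(rs@reads)
    names(seqs) <- names(rs@reads)
    out <- .kspectrum_correct_cpp(seqs, k, as.integer(trustThreshold),
                                  as.integer(passes))
    new_corrected(names(seqs), unname(out), "kspectrum",
                  list(k = k, trust_threshold = trustThreshold,
                       passes = passes))
}

#' Canonical k-mer census of a readset
#'
#' Counts every k-mer of the readset, pooling each k-mer with its reverse
#' complement (reads come from both strands). Exposed mainly for
#' inspection and testing of [kspectrumCorrect()].
#'
#' @param rs A [SimulatedReadset-class].
#' @param k K-mer length in \code{[1, 31]}.
#' @return \code{data.frame} with columns \code{kmer} (canonical form) and
#'   \code{count}.
#' @export
kmerCensus <- function(rs, k = 15L) {
    stopifnot(is(rs, "SimulatedReadset"))
    k <- as.integer(k)
    if (k < 1 || k > 31) stop("k must lie in [1, 31]")
    .kmer_census(as.character(rs@reads), k)
}

#' Ingest an externally corrected FASTQ
#'
#' Matches corrected records to the original readset by read id (the first
#' whitespace-delimited token of the FASTQ header). Ids present in the
#' readset but absent from the file are treated as removed reads; an id in
#' the file that the readset does not know, or a duplicated id, signals a
#' truth/readset mismatch and is a hard error.
#'
#' @param fastqPath Path to the corrected FASTQ.
#' @param rs The original [SimulatedReadset-class].
#' @param corrector Label to record (default "external").
#' @return A [CorrectedReadset-class].
#' @export
loadExternalCorrected <- function(fastqPath, rs, corrector = "external") {
    stopifnot(is(rs, "SimulatedReadset"))
    seqs <- Biostrings::readDNAStringSet(fastqPath, format = "fastq")
    ids <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(ids))
        stop("duplicate read ids in corrected FASTQ: ",
             ids[duplicated(ids)][1])
    unknown <- setdiff(ids, rs@truth$read_id)
    if (length(unknown))
        stop("corrected FASTQ contains ids not in the readset (first: ",
             unknown[1], ") - truth/readset mismatch")
    orig <- Biostrings::width(rs@reads)[match(ids, names(rs@reads))]
    if (any(Biostrings::width(seqs) > orig))
        stop("a corrected read is longer than its original")
    names(seqs) <- ids
    new("CorrectedReadset", records = seqs, corrector = corrector,
        params = list(path = fastqPath))
}
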