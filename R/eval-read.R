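#' Call heterozygous markers on corrected reads
#'
#' A heterozygous marker is any position of a surviving (post-trim) read
#' that overlaps a heterozygous site, whatever base it carries. Each
#' marker is assigned \code{"A"} if the corrected base (complemented to
#' genome frame on minus-strand reads) equals haplotype A's base,
#' \code{"B"} if it equals haplotype B's, and \code{"NEITHER"} otherwise.
#' Marker positions come from the truth ledger, not from re-alignment:
#' the simulator knows where every read came from.
#'
#' @param rs The original [SimulatedReadset-class].
#' @param pair The [HaplotypePair-class].
#' @param corrected A [CorrectedReadset-class]; removed reads yield no
#'   markers.
#' @return \code{data.frame} with columns \code{read_id}, \code{genome_pos}
#'   (0-based), \code{read_offset} (0-based, post-trim coordinates) and
#'   \code{assigned} ("A", "B" or "NEITHER").
#' @export
markerCalls <- function(rs, pair, corrected) {
    stopifnot(is(rs, "SimulatedReadset"), is(pair, "HaplotypePair"),
              is(corrected, "CorrectedReadset"))
    tr <- rs@truth
    hs <- hetSites(pair)
    empty <- data.frame(read_id = character(), genome_pos = integer(),
                        read_offset = integer(), assigned = character(),
                        stringsAsFactors = FALSE)
    if (!nrow(hs)) return(empty)
    trims <- infer_trim_all(rs, corrected)

    # surviving genome span of each read, half-open [lo, hi)
    surv <- !trims$removed
    lo <- integer(nrow(tr)); hi <- integer(nrow(tr))
    neg <- tr$strand == "-"
    lo[!neg] <- tr$start[!neg] + trims$trim_start[!neg]
    hi[!neg] <- tr$start[!neg] + tr$length[!neg] - trims$trim_end[!neg]
    lo[neg]  <- tr$start[neg] + trims$trim_end[neg]
    hi[neg]  <- tr$start[neg] + tr$length[neg] - trims$trim_start[neg]
    width <- ifelse(surv, hi - lo, 0L)
    if (!any(width > 0L)) return(empty)

    ov <- IRanges::findOverlaps(
        IRanges::IRanges(hs$pos + 1L, width = 1L),
        IRanges::IRanges(lo + 1L, width = pmax(width, 0L)))
    si <- S4Vectors::queryHits(ov)
    ri <- S4Vectors::subjectHits(ov)
    if (!length(ri)) return(empty)
    gpos <- hs$pos[si]
    rneg <- neg[ri]
    off  <- ifelse(rneg, tr$start[ri] + tr$length[ri] - 1L - gpos,
                   gpos - tr$start[ri])                 # original offset
    post <- as.integer(off - trims$trim_start[ri])      # post-trim offset
    corrSeqs <- as.character(corrected@records)
    cm <- match(tr$read_id, names(corrected@records))
    base <- substring(corrSeqs[cm[ri]], post + 1L, post + 1L)
    base[rneg] <- complement_base(base[rneg])           # genome frame
    assigned <- ifelse(base == hs$baseA[si], "A",
                ifelse(base == hs$baseB[si], "B", "NEITHER"))
    ord <- order(ri, gpos)
    data.frame(read_id = tr$read_id[ri][ord], genome_pos = gpos[ord],
               read_offset = post[ord], assigned = assigned[ord],
               stringsAsFactors = FALSE)
}

#' Is a marker pattern chimeric?
#'
#' A chimeric read must carry more than one heterozygous marker and have
#' both haplotypes represented among them. Markers assigned to neither
#' haplotype count toward the marker total but represent no haplotype, so
#' they can never make a read chimeric on their own.
#'
#' @param assigned Character vector of marker assignments for one read,
#'   each "A", "B" or "NEITHER".
#' @return \code{TRUE} iff there are more than one marker and at least one
#'   "A" and one "B" among them.
#' @examples
#' isChimeric(c("A", "B"))        # TRUE
#' isChimeric(c("A", "A", "A"))   # FALSE
#' isChimeric(c("A", "NEITHER"))  # FALSE
#' @export
isChimeric <- function(assigned) {
    length(assigned) > 1 && any(assigned == "A") && any(assigned == "B")
}

#' Read-level chimera statistics of a corrected readset
#'
#' Calls markers on every surviving read ([markerCalls()]) and counts
#' multimarker reads (more than one marker) and chimeric reads among them.
#' Removed reads count toward the read total but can be neither
#' multimarker nor chimeric.
#'
#' @param rs The original [SimulatedReadset-class].
#' @param pair The [HaplotypePair-class].
#' @param corrected A [CorrectedReadset-class].
#' @return A [ChimeraReport-class].
#' @export
chimeraReport <- function(rs, pair, corrected) {
    mc <- markerCalls(rs, pair, corrected)
    nTotal <- nrow(rs@truth)
    if (!nrow(mc)) {
        return(new("ChimeraReport", nReadsTotal = as.integer(nTotal),
                   nMultimarker = 0L, nChimeric = 0L,
                   meta = list(corrector = corrected@corrector,
                               het_rate = hetRate(pair))))
    }
    byRead <- split(mc$assigned, mc$read_id)
    multi <- lengths(byRead) > 1L
    chim <- vapply(byRead[multi],
                   function(a) any(a == "A") && any(a == "B"), logical(1))
    new("ChimeraReport",
        nReadsTotal = as.integer(nTotal),
        nMultimarker = as.integer(sum(multi)),
        nChimeric = as.integer(sum(chim)),
        meta = list(corrector = corrected@corrector,
                    het_rate = hetRate(pair)))
}

#' @describeIn ChimeraReport-class Chimeric reads out of all multimarker
#'   reads; \code{NA} when no read has more than one marker.
#' @param x,object A \code{ChimeraReport}.
#' @export
rateChimeric <- function(x) {
    if (x@nMultimarker == 0L) return(NA_real_)
    x@nChimeric / x@nMultimarker
}

#' @describeIn ChimeraReport-class Multimarker reads out of all reads.
#' @export
rateMultimarker <- function(x) {
    if (x@nReadsTotal == 0L) return(NA_real_)
    x@nMultimarker / x@nReadsTotal
}

setMethod("show", "ChimeraReport", function(object) {
    cat("ChimeraReport (", object@meta$corrector, ")\n", sep = "")
    cat(sprintf("  reads: %d total, %d multimarker, %d chimeric\n",
                object@nReadsTotal, object@nMultimarker, object@nChimeric))
    rc <- rateChimeric(object)
    cat(sprintf("  chimera rate among multimarker reads: %s\n",
                ifelse(is.na(rc), "NA", sprintf("%.4f", rc))))
})

#' @describeIn ChimeraReport-class One-row data.frame of the counts and
#'   rates.
#' @param row.names,optional,... Passed on conventionally; unused.
#' @export
setMethod("as.data.frame", "ChimeraReport",
    function(x, row.names = NULL, optional = FALSE, ...) {
        data.frame(het_rate = x@meta$het_rate,
                   corrector = x@meta$corrector,
                   n_reads_total = x@nReadsTotal,
                   n_multimarker = x@nMultimarker,
                   n_chimeric = x@nChimeric,
                   rate_chimeric = rateChimeric(x),
                   rate_multimarker = rateMultimarker(x),
                   stringsAsFactors = FALSE)
    })
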