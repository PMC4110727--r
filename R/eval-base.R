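#' Infer end-trimming of a corrected read
#'
#' Corrected FASTQ carries no trim coordinates, so trimming must be
#' inferred. Among all splits \code{(ts, te)} with
#' \code{ts + te == length(original) - length(corrected)}, the pair
#' minimising the Hamming distance between
#' \code{original[ts+1 .. len-te]} and the corrected sequence is returned;
#' ties break to the smallest \code{ts}. An absent record means the read
#' was removed. Only end-trimming is in model (interior deletions are
#' not): a corrected sequence longer than the original is an error.
#'
#' @param original Original read sequence (single string).
#' @param corrected Corrected sequence, or \code{NA}/\code{NULL} if the
#'   read was removed.
#' @return A list with \code{removed} (logical), \code{trim_start} and
#'   \code{trim_end} (both 0 when \code{removed}).
#' @examples
#' inferTrim("AAAAATTTTT", "AAATTTTT")   # trim_start 2, trim_end 0
#' @export
inferTrim <- function(original, corrected) {
    if (is.null(corrected) || length(corrected) == 0 || is.na(corrected))
        return(list(removed = TRUE, trim_start = 0L, trim_end = 0L))
    lo <- nchar(original); lc <- nchar(corrected)
    if (lc > lo)
        stop("corrected sequence longer than original: not an end-trim")
    dL <- lo - lc
    if (dL == 0L)
        return(list(removed = FALSE, trim_start = 0L, trim_end = 0L))
    ts <- 0:dL
    cand <- substring(original, ts + 1L, lo - (dL - ts))
    ham <- str_hamming(cand, rep(corrected, dL + 1L))
    best <- which.min(ham)  # first minimum = smallest ts
    list(removed = FALSE, trim_start = ts[best],
         trim_end = dL - ts[best])
}

# Vectorised trim inference over a whole readset; returns a data.frame
# aligned with truth rows: removed, trim_start, trim_end.
infer_trim_all <- function(rs, corrected) {
    tr <- rs@truth
    orig <- as.character(rs@reads)[match(tr$read_id, names(rs@reads))]
    cm <- match(tr$read_id, names(corrected@records))
    removed <- is.na(cm)
    ts <- integer(nrow(tr)); te <- integer(nrow(tr))
    if (any(!removed)) {
        corr <- as.character(corrected@records)[cm[!removed]]
        lo <- nchar(orig[!removed]); lc <- nchar(corr)
        if (any(lc > lo))
            stop("corrected sequence longer than original: not an end-trim")
        dL <- lo - lc
        idx <- which(!removed)
        for (d in sort(unique(dL[dL > 0L]))) {
            sel <- which(dL == d)
            bestH <- rep(Inf, length(sel)); bestT <- integer(length(sel))
            for (t in 0:d) {
                cand <- substring(orig[idx[sel]], t + 1L, lo[sel] - (d - t))
                h <- str_hamming(cand, corr[sel])
                upd <- h < bestH
                bestH[upd] <- h[upd]; bestT[upd] <- t
            }
            ts[idx[sel]] <- bestT
            te[idx[sel]] <- d - bestT
        }
    }
    data.frame(read_id = tr$read_id, removed = removed,
               trim_start = ts, trim_end = te, stringsAsFactors = FALSE)
}

#' Classify one base's treatment by a corrector
#'
#' The base-level outcome taxonomy. All bases are given in the same frame
#' (for minus-strand reads, complement to genome frame before calling, or
#' pass read-frame values consistently). \code{correctedBase = NA} means
#' the base was trimmed away or its read removed. The "unchanged" test
#' takes precedence over haplotype matching: an error base that happens to
#' equal the other haplotype's base and is left alone is "not corrected",
#' not "wrong haplotype".
#'
#' Outcomes by stratum:
#' \itemize{
#'   \item het/error: \code{corrected_correctly}, \code{not_corrected},
#'     \code{wrong_haplotype}, \code{neither_haplotype}, \code{trimmed}
#'   \item hom/error: \code{corrected_correctly}, \code{not_corrected},
#'     \code{miscorrected}, \code{trimmed}
#'   \item het/non-error: \code{unchanged}, \code{wrong_haplotype},
#'     \code{neither_haplotype}, \code{trimmed}
#'   \item hom/non-error: \code{unchanged}, \code{miscorrected},
#'     \code{trimmed}
#' }
#'
#' @param originalBase Base as written in the uncorrected read.
#' @param correctedBase Base after correction, or \code{NA} if trimmed or
#'   removed.
#' @param trueBase The source genome's base at this position.
#' @param otherHapBase The homologous haplotype's base when the position is
#'   heterozygous, else \code{NA}.
#' @param wasError Logical: was the written base an injected error
#'   (\code{originalBase != trueBase})?
#' @return Character vector of outcomes (vectorised over its arguments).
#' @export
classifyBase <- function(originalBase, correctedBase, trueBase,
                         otherHapBase, wasError) {
    n <- max(length(originalBase), length(correctedBase), length(trueBase),
             length(otherHapBase), length(wasError))
    o  <- rep_len(originalBase, n)
    c_ <- rep_len(correctedBase, n)
    t_ <- rep_len(trueBase, n)
    h  <- rep_len(otherHapBase, n)
    e  <- rep_len(wasError, n)
    ok <- is.na(c_) | c_ %in% VALID_BASES
    if (!all(ok))
        stop("corrected base outside {A,C,G,T}: ", c_[!ok][1])
    if (any(e & o == t_))
        stop("wasError implies originalBase != trueBase")
    het <- !is.na(h)
    out <- character(n)
    trimmed <- is.na(c_)
    out[trimmed] <- OUTCOMES["trimmed"]
    i <- !trimmed
    unchanged <- i & c_ == o
    out[unchanged &  e] <- OUTCOMES["not_corrected"]
    out[unchanged & !e] <- OUTCOMES["unchanged"]
    ch <- i & !unchanged             # actually modified
    out[ch & c_ == t_] <- OUTCOMES["corrected_correctly"]   # only possible if e
    rest <- ch & c_ != t_
    out[rest &  het & c_ == h] <- OUTCOMES["wrong_haplotype"]
    out[rest &  het & c_ != h] <- OUTCOMES["neither_haplotype"]
    out[rest & !het]           <- OUTCOMES["miscorrected"]
    # a modified non-error het base equal to trueBase cannot occur
    # (c_ == t_ == o implies unchanged); a modified hom non-error likewise.
    unname(out)
}

# Enumerate every base to classify: all injected errors plus all het-site
# overlaps. Returns a data.frame in genome frame with one row per event.
enumerate_events <- function(rs, pair) {
    tr <- rs@truth
    err <- rs@errors
    hs <- hetSites(pair)
    neg <- tr$strand == "-"

    evErr <- NULL
    if (nrow(err)) {
        ri <- match(err$read_id, tr$read_id)
        en <- neg[ri]
        gpos <- ifelse(en, tr$start[ri] + tr$length[ri] - 1L - err$offset,
                       tr$start[ri] + err$offset)
        evErr <- data.frame(read = ri, offset = err$offset, gpos = gpos,
                            was_error = TRUE, stringsAsFactors = FALSE)
    }
    evHet <- NULL
    if (nrow(hs)) {
        ov <- IRanges::findOverlaps(
            IRanges::IRanges(hs$pos + 1L, width = 1L),
            IRanges::IRanges(tr$start + 1L, width = tr$length))
        si <- S4Vectors::queryHits(ov)
        ri <- S4Vectors::subjectHits(ov)
        gpos <- hs$pos[si]
        en <- neg[ri]
        off <- ifelse(en, tr$start[ri] + tr$length[ri] - 1L - gpos,
                      gpos - tr$start[ri])
        evHet <- data.frame(read = ri, offset = as.integer(off),
                            gpos = gpos,
                            was_error = rep(FALSE, length(ri)),
                            stringsAsFactors = FALSE)
        if (!is.null(evErr) && nrow(evHet)) {
            # het events that are injected errors are already in evErr
            dup <- paste(evHet$read, evHet$offset) %in%
                   paste(evErr$read, evErr$offset)
            evHet <- evHet[!dup, , drop = FALSE]
        }
    }
    ev <- rbind(evErr, evHet)
    if (is.null(ev) || !nrow(ev))
        return(data.frame(read = integer(), offset = integer(),
                          gpos = integer(), was_error = logical(),
                          zygosity = character(), stringsAsFactors = FALSE))
    ev$zygosity <- ifelse(ev$gpos %in% hs$pos, "het", "hom")
    ev
}

#' Evaluate a corrected readset base by base
#'
#' Walks every ground-truth error base and every base overlapping a
#' heterozygous site, maps read offsets to genome positions strand-aware,
#' infers end-trimming per read (see [inferTrim()]), and classifies each
#' base with [classifyBase()]. Bases lost to trimming — including all
#' classified bases of removed reads — fall into the \code{trimmed} class,
#' accounted separately from "not corrected".
#'
#' @param rs The original [SimulatedReadset-class].
#' @param pair The [HaplotypePair-class].
#' @param corrected A [CorrectedReadset-class] matched to \code{rs} by read
#'   id.
#' @return An [EvaluationReport-class].
#' @examples
#' pair <- introduceHeterozygosity(randomReference(2000, 1), 0.02, seed = 2)
#' rs <- simulateReads(pair, coverage = 5, errorRate = 0.04, seed = 3)
#' rep <- evaluateCorrections(rs, pair, oracleCorrect(rs))
#' rateCorrected(rep, "corrected_correctly")   # 1 by construction
#' @export
evaluateCorrections <- function(rs, pair, corrected) {
    stopifnot(is(rs, "SimulatedReadset"), is(pair, "HaplotypePair"),
              is(corrected, "CorrectedReadset"))
    if (length(setdiff(names(corrected@records), rs@truth$read_id)))
        stop("corrected readset contains unknown read ids")
    tr <- rs@truth
    trims <- infer_trim_all(rs, corrected)
    ev <- enumerate_events(rs, pair)

    outcome <- character(nrow(ev))
    if (nrow(ev)) {
        hapA <- as.character(pair@hapA)
        hapB <- as.character(pair@hapB)
        origSeqs <- as.character(rs@reads)[match(tr$read_id,
                                                 names(rs@reads))]
        corrSeqs <- as.character(corrected@records)
        cm <- match(tr$read_id, names(corrected@records))

        r <- ev$read
        neg <- tr$strand[r] == "-"
        srcA <- tr$haplotype[r] == "A"
        p1 <- ev$gpos + 1L
        trueB  <- ifelse(srcA, substring(hapA, p1, p1),
                               substring(hapB, p1, p1))
        otherB <- ifelse(ev$zygosity == "het",
                         ifelse(srcA, substring(hapB, p1, p1),
                                      substring(hapA, p1, p1)),
                         NA_character_)
        origB <- substring(origSeqs[r], ev$offset + 1L, ev$offset + 1L)
        origB[neg] <- complement_base(origB[neg])       # genome frame

        surv <- !trims$removed[r] &
                ev$offset >= trims$trim_start[r] &
                ev$offset < tr$length[r] - trims$trim_end[r]
        corrB <- rep(NA_character_, nrow(ev))
        if (any(surv)) {
            cpos <- ev$offset[surv] - trims$trim_start[r][surv] + 1L
            corrB[surv] <- substring(corrSeqs[cm[r][surv]], cpos, cpos)
            flipme <- surv & neg
            corrB[flipme] <- complement_base(corrB[flipme])
        }
        outcome <- classifyBase(origB, corrB, trueB, otherB, ev$was_error)
    }

    strata <- list(
        het_error     = c("corrected_correctly", "not_corrected",
                          "wrong_haplotype", "neither_haplotype", "trimmed"),
        hom_error     = c("corrected_correctly", "not_corrected",
                          "miscorrected", "trimmed"),
        het_non_error = c("unchanged", "wrong_haplotype",
                          "neither_haplotype", "trimmed"),
        hom_non_error = c("unchanged", "miscorrected", "trimmed"))
    key <- paste0(ev$zygosity, ifelse(ev$was_error, "_error", "_non_error"))
    counts <- do.call(rbind, lapply(names(strata), function(s) {
        zt <- strsplit(s, "_")[[1]]
        oc <- strata[[s]]
        n <- vapply(oc, function(o) sum(key == s & outcome == o), integer(1))
        data.frame(zygosity = zt[1],
                   truth_status = paste(zt[-1], collapse = "_"),
                   outcome = oc, count = n,
                   stringsAsFactors = FALSE, row.names = NULL)
    }))
    new("EvaluationReport", counts = counts,
        meta = list(het_rate = hetRate(pair),
                    error_rate = rs@params$error_rate,
                    corrector = corrected@corrector,
                    n_reads = nrow(tr),
                    n_events = nrow(ev)))
}

#' @describeIn EvaluationReport-class The full (zygosity, truth status,
#'   outcome) count table.
#' @export
outcomeCounts <- function(x) x@counts

#' @describeIn EvaluationReport-class Evaluation metadata list.
#' @export
reportMeta <- function(x) x@meta

stratum_counts <- function(report, zygosity, truth_status) {
    cc <- report@counts
    cc[cc$zygosity %in% zygosity & cc$truth_status == truth_status, ,
       drop = FALSE]
}

#' Outcome rates of an evaluation
#'
#' The three rate families reported per dataset:
#' \describe{
#'   \item{\code{rateCorrected(report, outcome)}}{the number of
#'     heterozygous \emph{error} bases with the given outcome out of all
#'     heterozygous error bases.}
#'   \item{\code{rateIntroduced(report)}}{mis-corrections at non-error
#'     heterozygous positions (corrected to the wrong or to neither
#'     haplotype) out of all non-error heterozygous positions — the rate
#'     at which correction injects new errors.}
#'   \item{\code{rateOccurrence(report, outcome)}}{how often an error —
#'     heterozygous and homozygous pooled — is treated a given way, out of
#'     all error bases. Here the outcome \code{"miscorrected"} pools
#'     wrong-haplotype, neither-haplotype and homozygous mis-corrections.}
#' }
#' A rate whose denominator is zero is undefined and returned as \code{NA},
#' never as 0.
#'
#' @param report An [EvaluationReport-class].
#' @param outcome Outcome name (see [classifyBase()]).
#' @return A single numeric rate in \code{[0, 1]}, or \code{NA}.
#' @name rates
NULL

#' @rdname rates
#' @export
rateCorrected <- function(report, outcome) {
    cc <- stratum_counts(report, "het", "error")
    tot <- sum(cc$count)
    if (tot == 0) return(NA_real_)
    sum(cc$count[cc$outcome == outcome]) / tot
}

#' @rdname rates
#' @export
rateIntroduced <- function(report) {
    cc <- stratum_counts(report, "het", "non_error")
    tot <- sum(cc$count)
    if (tot == 0) return(NA_real_)
    sum(cc$count[cc$outcome %in%
                 c("wrong_haplotype", "neither_haplotype")]) / tot
}

#' @rdname rates
#' @export
rateOccurrence <- function(report, outcome) {
    cc <- stratum_counts(report, c("het", "hom"), "error")
    tot <- sum(cc$count)
    if (tot == 0) return(NA_real_)
    oc <- if (outcome == "miscorrected")
        c("wrong_haplotype", "neither_haplotype", "miscorrected")
    else outcome
    sum(cc$count[cc$outcome %in% oc]) / tot
}

setMethod("show", "EvaluationReport", function(object) {
    m <- object@meta
    cat("EvaluationReport (", m$corrector, ")\n", sep = "")
    cat(sprintf("  het rate %.4g, error rate %.4g, %d reads, %d bases\n",
                m$het_rate, m$error_rate, m$n_reads, m$n_events))
    rc <- rateCorrected(object, "corrected_correctly")
    ri <- rateIntroduced(object)
    cat(sprintf("  het errors corrected correctly: %s\n",
                ifelse(is.na(rc), "NA", sprintf("%.3f", rc))))
    cat(sprintf("  errors introduced at het non-error bases: %s\n",
                ifelse(is.na(ri), "NA", sprintf("%.3f", ri))))
})

#' @describeIn EvaluationReport-class Long-format data.frame of counts and
#'   within-stratum rates, ready for aggregation across configurations.
#' @param row.names,optional,... Passed on conventionally; unused.
#' @export
setMethod("as.data.frame", "EvaluationReport",
    function(x, row.names = NULL, optional = FALSE, ...) {
        cc <- x@counts
        tot <- stats::ave(cc$count, cc$zygosity, cc$truth_status, FUN = sum)
        cc$rate <- ifelse(tot > 0, cc$count / tot, NA_real_)
        m <- x@meta
        data.frame(het_rate = m$het_rate, error_rate = m$error_rate,
                   corrector = m$corrector, cc,
                   stringsAsFactors = FALSE)
    })
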