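# Shared fixture builders and independent brute-force oracles. Everything
# here is written naively (per-base loops, exhaustive enumeration) on
# purpose: these are the reference implementations the vectorised package
# code is tested against, and they must not share its code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

COMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_naive <- function(s) {
    paste(rev(COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# A small diploid + readset fixture with everything truth-tracked.
tiny_fixture <- function(L = 2000, het = 0.02, readLength = 30,
                         coverage = 8, errorRate = 0.03, seed = 42) {
    pair <- introduceHeterozygosity(randomReference(L, seed), het,
                                    seed = seed + 1)
    rs <- simulateReads(pair, readLength = readLength, coverage = coverage,
                        errorRate = errorRate, seed = seed + 2)
    list(pair = pair, rs = rs)
}

# Brute-force trim inference: try every split naively.
brute_trim <- function(orig, corr) {
    if (is.null(corr) || is.na(corr))
        return(list(removed = TRUE, trim_start = 0L, trim_end = 0L))
    dL <- nchar(orig) - nchar(corr)
    bestT <- 0L; bestH <- Inf
    for (t in 0:dL) {
        sub <- substring(orig, t + 1, nchar(orig) - (dL - t))
        h <- sum(strsplit(sub, "")[[1]] != strsplit(corr, "")[[1]])
        if (h < bestH) { bestH <- h; bestT <- t }
    }
    list(removed = FALSE, trim_start = bestT, trim_end = dL - bestT)
}

# Brute-force base-level evaluation: walk every read, every offset, one
# base at a time. Returns a named count vector keyed
# "zygosity|truth_status|outcome".
brute_evaluate <- function(rs, pair, corrected) {
    tr <- truthTable(rs)
    err <- errorTable(rs)
    hs <- hetSites(pair)
    hapStr <- c(A = as.character(hapA(pair)), B = as.character(hapB(pair)))
    recs <- records(corrected)
    counts <- list()
    bump <- function(zyg, st, oc) {
        key <- paste(zyg, st, oc, sep = "|")
        counts[[key]] <<- (counts[[key]] %||% 0L) + 1L
    }
    for (i in seq_len(nrow(tr))) {
        id <- tr$read_id[i]
        orig <- as.character(reads(rs)[[id]])
        has <- id %in% names(recs)
        corr <- if (has) as.character(recs[[id]]) else NA
        trim <- brute_trim(orig, corr)
        myerr <- err[err$read_id == id, , drop = FALSE]
        for (off in 0:(tr$length[i] - 1)) {
            gpos <- if (tr$strand[i] == "+") tr$start[i] + off
                    else tr$start[i] + tr$length[i] - 1 - off
            j <- match(gpos, hs$pos)
            isHet <- !is.na(j)
            isErr <- off %in% myerr$offset
            if (!isHet && !isErr) next
            src <- tr$haplotype[i]
            sB <- substring(hapStr[src], gpos + 1, gpos + 1)
            oB <- if (!isHet) NA_character_
                  else if (src == "A") hs$baseB[j] else hs$baseA[j]
            ob <- substring(orig, off + 1, off + 1)
            if (tr$strand[i] == "-") ob <- COMP[[ob]]
            surv <- !trim$removed && off >= trim$trim_start &&
                    off < tr$length[i] - trim$trim_end
            cb <- NA_character_
            if (surv) {
                cb <- substring(corr, off - trim$trim_start + 1,
                                off - trim$trim_start + 1)
                if (tr$strand[i] == "-") cb <- COMP[[cb]]
            }
            zyg <- if (isHet) "het" else "hom"
            st <- if (isErr) "error" else "non_error"
            oc <- if (is.na(cb)) "trimmed"
                  else if (cb == ob) { if (isErr) "not_corrected"
                                       else "unchanged" }
                  else if (cb == sB) "corrected_correctly"
                  else if (isHet && cb == oB) "wrong_haplotype"
                  else if (isHet) "neither_haplotype"
                  else "miscorrected"
            bump(zyg, st, oc)
        }
    }
    unlist(counts) %||% integer()
}

# EvaluationReport counts in the same "zyg|status|outcome" keying, zero
# rows dropped, for comparison against brute_evaluate().
report_as_keys <- function(report) {
    cc <- outcomeCounts(report)
    cc <- cc[cc$count > 0, , drop = FALSE]
    out <- cc$count
    names(out) <- paste(cc$zygosity, cc$truth_status, cc$outcome, sep = "|")
    out[order(names(out))]
}

# Brute-force chimera decision over a vector of marker assignments.
brute_chimeric <- function(assigned) {
    if (length(assigned) <= 1) return(FALSE)
    haps <- unique(assigned[assigned %in% c("A", "B")])
    length(haps) == 2
}
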