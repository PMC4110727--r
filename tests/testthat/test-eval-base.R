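test_that("trim inference finds the Hamming-minimal end split", {
    expect_equal(inferTrim("ACGTACGT", "ACGTACGT"),
                 list(removed = FALSE, trim_start = 0L, trim_end = 0L))
    # candidates (0,2),(1,1),(2,0) give Hamming 2,1,0
    expect_equal(inferTrim("AAAAATTTTT", "AAATTTTT"),
                 list(removed = FALSE, trim_start = 2L, trim_end = 0L))
    expect_equal(inferTrim("AAAAATTTTT", NA),
                 list(removed = TRUE, trim_start = 0L, trim_end = 0L))
    expect_error(inferTrim("ACG", "ACGT"), "longer")
    # ties break to the smallest trim_start
    expect_equal(inferTrim("AAAA", "AAA")$trim_start, 0L)
    # randomized agreement with the brute-force enumerator
    set.seed(31)
    for (i in 1:50) {
        orig <- paste(sample(c("A","C","G","T"), 20, TRUE), collapse = "")
        d <- sample(0:6, 1)
        ts <- sample(0:d, 1)
        corr <- substring(orig, ts + 1, 20 - (d - ts))
        expect_equal(inferTrim(orig, corr), brute_trim(orig, corr))
    }
})

test_that("classifyBase matches an exhaustive truth table over all base combos", {
    bases <- c("A", "C", "G", "T")
    # hand rules, written independently of the implementation
    expected_outcome <- function(o, cb, t, h, e) {
        if (is.na(cb)) return("trimmed")
        if (cb == o) return(if (e) "not_corrected" else "unchanged")
        if (e && cb == t) return("corrected_correctly")
        if (!is.na(h)) {
            if (cb == h) return("wrong_haplotype")
            return("neither_haplotype")
        }
        "miscorrected"
    }
    n <- 0
    for (t in bases) for (o in bases) {
        for (h in c(bases[bases != t], NA)) {      # het other base or hom
            for (cb in c(bases, NA)) {
                e <- o != t                         # error iff written != true
                got <- classifyBase(o, cb, t, h, e)
                expect_identical(got, expected_outcome(o, cb, t, h, e),
                                 label = paste(o, cb, t, h, e))
                n <- n + 1
            }
        }
    }
    expect_equal(n, 4 * 4 * 4 * 5)   # full cross-product was covered
    expect_error(classifyBase("A", "N", "C", NA, TRUE), "outside")
    expect_error(classifyBase("A", "A", "A", NA, TRUE), "wasError")
})

test_that("unchanged takes precedence over haplotype matching", {
    # het site: true 'A', other 'C'; error read base 'C' (mimics the other
    # haplotype) left as-is is NOT_CORRECTED, not wrong_haplotype
    expect_identical(classifyBase("C", "C", "A", "C", TRUE),
                     "not_corrected")
    expect_identical(classifyBase("G", "A", "A", "C", TRUE),
                     "corrected_correctly")
    expect_identical(classifyBase("G", "C", "A", "C", TRUE),
                     "wrong_haplotype")
    expect_identical(classifyBase("G", "T", "A", "C", TRUE),
                     "neither_haplotype")
})

test_that("evaluateCorrections matches the brute-force enumerator", {
    set.seed(202)
    for (i in 1:40) {
        L <- sample(30:50, 1)
        pair <- introduceHeterozygosity(randomReference(L, i), 0.1,
                                        seed = i)
        rl <- sample(10:20, 1)
        rs <- simulateReads(pair, readLength = rl,
                            coverage = runif(1, 2, 4),
                            errorRate = runif(1, 0, 0.2), seed = i + 500)
        corrector <- switch(1 + (i %% 4),
            oracleCorrect(rs),
            identityCorrect(rs),
            trimCorrect(rs, sample(0:3, 1), sample(0:3, 1)),
            flipMarkersCorrect(rs, pair, 0.5, seed = i))
        rep <- evaluateCorrections(rs, pair, corrector)
        brute <- brute_evaluate(rs, pair, corrector)
        expect_equal(report_as_keys(rep), brute[order(names(brute))],
                     label = paste("instance", i))
    }
})

test_that("per-stratum outcome counts always sum to the stratum total", {
    fx <- tiny_fixture(het = 0.05, errorRate = 0.05)
    for (co in list(oracleCorrect(fx$rs), identityCorrect(fx$rs),
                    trimCorrect(fx$rs, 6, 4),
                    kspectrumCorrect(fx$rs, 13, 2))) {
        rep <- evaluateCorrections(fx$rs, fx$pair, co)
        cc <- outcomeCounts(rep)
        # within each stratum the rates are a partition of 1
        for (zyg in c("het", "hom")) for (st in c("error", "non_error")) {
            sub <- cc[cc$zygosity == zyg & cc$truth_status == st, ]
            if (sum(sub$count) > 0) {
                df <- as.data.frame(rep)
                r <- df$rate[df$zygosity == zyg & df$truth_status == st]
                expect_equal(sum(r), 1)
            }
        }
        # het error outcome rates via rateCorrected also sum to 1
        hetOut <- c("corrected_correctly", "not_corrected",
                    "wrong_haplotype", "neither_haplotype", "trimmed")
        expect_equal(sum(vapply(hetOut, function(o) rateCorrected(rep, o),
                                numeric(1))), 1)
    }
})

test_that("oracle and identity correctors produce their textbook rates", {
    fx <- tiny_fixture(het = 0.04, errorRate = 0.05)
    orep <- evaluateCorrections(fx$rs, fx$pair, oracleCorrect(fx$rs))
    expect_equal(rateCorrected(orep, "corrected_correctly"), 1.0)
    expect_equal(rateOccurrence(orep, "corrected_correctly"), 1.0)
    expect_equal(rateIntroduced(orep), 0)
    irep <- evaluateCorrections(fx$rs, fx$pair, identityCorrect(fx$rs))
    expect_equal(rateCorrected(irep, "not_corrected"), 1.0)
    expect_equal(rateOccurrence(irep, "not_corrected"), 1.0)
    expect_equal(rateIntroduced(irep), 0)
})

test_that("errors removed by trimming land in the trimmed class", {
    # build reads whose errors all sit in the first 10 bases, then trim
    pair <- introduceHeterozygosity(randomReference(400, 3), 0.02, seed = 4)
    rs <- simulateReads(pair, readLength = 40, coverage = 6,
                        errorRate = 0, seed = 5)
    seqs <- as.character(reads(rs))
    ids <- names(seqs)
    # inject one error at offset 4 of every read, by hand
    old <- substring(seqs, 5, 5)
    wrong <- COMP[old]   # complement always differs
    seqs <- paste0(substring(seqs, 1, 4), wrong, substring(seqs, 6))
    rs@reads <- Biostrings::DNAStringSet(seqs)
    names(rs@reads) <- ids
    rs@errors <- data.frame(read_id = ids, offset = 4L, true_base = old,
                            stringsAsFactors = FALSE)
    stopifnot(verifyReadset(rs, pair))
    rep <- evaluateCorrections(rs, pair, trimCorrect(rs, 10, 10))
    expect_equal(rateOccurrence(rep, "trimmed"), 1.0)
    # removed reads contribute all their classified bases as trimmed
    rep2 <- evaluateCorrections(rs, pair, trimCorrect(rs, 30, 10))
    expect_equal(rateOccurrence(rep2, "trimmed"), 1.0)
})

test_that("zero denominators yield NA rates, not 0", {
    pair <- introduceHeterozygosity(randomReference(300, 8), 0, seed = 1)
    rs <- simulateReads(pair, readLength = 30, coverage = 4,
                        errorRate = 0, seed = 2)
    rep <- evaluateCorrections(rs, pair, identityCorrect(rs))
    expect_true(is.na(rateCorrected(rep, "corrected_correctly")))
    expect_true(is.na(rateIntroduced(rep)))
    expect_true(is.na(rateOccurrence(rep, "not_corrected")))
})

test_that("mirrored strands give identical reports", {
    fx <- tiny_fixture(het = 0.05, errorRate = 0)
    rs <- fx$rs
    # force all reads to '+' by reverse-complementing the '-' ones
    neg <- rs@truth$strand == "-"
    seqs <- as.character(reads(rs))
    seqs[neg] <- vapply(seqs[neg], revcomp_naive, character(1))
    plus <- rs
    plus@reads <- Biostrings::DNAStringSet(seqs)
    names(plus@reads) <- rs@truth$read_id
    plus@truth$strand <- "+"
    stopifnot(verifyReadset(plus, fx$pair))
    repA <- evaluateCorrections(rs, fx$pair,
                                flipMarkersCorrect(rs, fx$pair, 1, seed = 3))
    repB <- evaluateCorrections(plus, fx$pair,
                                flipMarkersCorrect(plus, fx$pair, 1, seed = 3))
    expect_equal(outcomeCounts(repA), outcomeCounts(repB))
})
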