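test_that("the oracle corrector restores every injected error and nothing else", {
    fx <- tiny_fixture(errorRate = 0.05)
    co <- oracleCorrect(fx$rs)
    expect_length(removedIds(co, fx$rs), 0)
    # oracle output equals the reconstruction from the truth ledger
    tr <- truthTable(fx$rs)
    hapStr <- c(A = as.character(hapA(fx$pair)),
                B = as.character(hapB(fx$pair)))
    expected <- substring(hapStr[tr$haplotype], tr$start + 1,
                          tr$start + tr$length)
    neg <- tr$strand == "-"
    expected[neg] <- vapply(expected[neg], revcomp_naive, character(1))
    got <- as.character(records(co))[tr$read_id]
    expect_identical(unname(got), unname(expected))

    # error-free readset: oracle is the identity
    fx0 <- tiny_fixture(errorRate = 0)
    expect_identical(as.character(records(oracleCorrect(fx0$rs))),
                     as.character(records(identityCorrect(fx0$rs))))
})

test_that("trimCorrect trims ends exactly and removes over-trimmed reads", {
    fx <- tiny_fixture(readLength = 30, errorRate = 0.02)
    id0 <- trimCorrect(fx$rs, 0, 0)
    expect_identical(as.character(records(id0)),
                     as.character(records(identityCorrect(fx$rs))))
    tc <- trimCorrect(fx$rs, 5, 3)
    expect_true(all(Biostrings::width(records(tc)) == 22))
    orig <- as.character(reads(fx$rs))
    expect_identical(unname(as.character(records(tc))),
                     unname(substring(orig, 6, 27)))
    gone <- trimCorrect(fx$rs, 20, 10)   # 20 + 10 >= 30
    expect_length(records(gone), 0)
    expect_setequal(removedIds(gone, fx$rs), truthTable(fx$rs)$read_id)
})

test_that("flipMarkersCorrect flips only non-error het bases at the set rate", {
    fx <- tiny_fixture(het = 0.05, errorRate = 0)
    f0 <- flipMarkersCorrect(fx$rs, fx$pair, 0, seed = 1)
    expect_identical(as.character(records(f0)),
                     as.character(records(identityCorrect(fx$rs))))
    f1 <- flipMarkersCorrect(fx$rs, fx$pair, 1, seed = 1)
    rep1 <- evaluateCorrections(fx$rs, fx$pair, f1)
    # with error-free reads and p=1 every het non-error base goes to the
    # other haplotype
    cc <- outcomeCounts(rep1)
    hn <- cc[cc$zygosity == "het" & cc$truth_status == "non_error", ]
    expect_gt(sum(hn$count), 0)
    expect_equal(sum(hn$count[hn$outcome == "wrong_haplotype"]),
                 sum(hn$count))
    # error bases are never touched
    fxe <- tiny_fixture(het = 0.05, errorRate = 0.05)
    fe <- flipMarkersCorrect(fxe$rs, fxe$pair, 1, seed = 2)
    err <- errorTable(fxe$rs)
    got <- as.character(records(fe))[err$read_id]
    orig <- as.character(reads(fxe$rs))[err$read_id]
    expect_identical(substring(got, err$offset + 1, err$offset + 1),
                     substring(orig, err$offset + 1, err$offset + 1))
})

test_that("control correctors commute with splitting by haplotype", {
    fx <- tiny_fixture(het = 0.04, errorRate = 0.04)
    halves <- splitByHaplotype(fx$rs)
    for (fun in list(
        function(r) oracleCorrect(r),
        function(r) identityCorrect(r),
        function(r) trimCorrect(r, 4, 2),
        function(r) flipMarkersCorrect(r, fx$pair, 0.5, seed = 9))) {
        pooled <- records(fun(fx$rs))
        split2 <- c(records(fun(halves$A)), records(fun(halves$B)))
        expect_identical(sort(names(pooled)), sort(names(split2)))
        expect_identical(as.character(pooled[sort(names(pooled))]),
                         as.character(split2[sort(names(pooled))]))
    }
})

test_that("kspectrum leaves an error-free high-coverage readset unchanged", {
    fx <- tiny_fixture(L = 5000, het = 0.01, readLength = 75,
                       coverage = 40, errorRate = 0)
    ks <- kspectrumCorrect(fx$rs, k = 15, trustThreshold = 2)
    census <- kmerCensus(fx$rs, 15)
    trusted <- census$kmer[census$count >= 2]
    # brute-force check of which reads have all k-mers trusted
    canon <- function(s) {
        rc <- revcomp_naive(s)
        if (rc < s) rc else s
    }
    orig <- as.character(reads(fx$rs))
    changedIds <- names(orig)[orig != as.character(records(ks))[names(orig)]]
    for (id in names(orig)[1:50]) {
        s <- orig[[id]]
        kms <- vapply(1:(nchar(s) - 14),
                      function(i) canon(substring(s, i, i + 14)),
                      character(1))
        if (all(kms %in% trusted)) expect_false(id %in% changedIds)
    }
    # at 40x nearly every k-mer occurs twice; no read should change
    expect_length(changedIds, 0)
})

test_that("kspectrum restores a single isolated error to the true base", {
    fx <- tiny_fixture(L = 5000, het = 0, readLength = 75, coverage = 40,
                       errorRate = 0)
    # corrupt exactly one base in the middle of one read
    rs <- fx$rs
    seqs <- as.character(reads(rs))
    old <- substring(seqs[1], 38, 38)
    wrong <- setdiff(c("A", "C", "G", "T"), old)[1]
    seqs[1] <- paste0(substring(seqs[1], 1, 37), wrong,
                      substring(seqs[1], 39, 75))
    rs@reads <- Biostrings::DNAStringSet(seqs)
    ks <- kspectrumCorrect(rs, k = 15, trustThreshold = 2)
    fixed <- as.character(records(ks))[[names(seqs)[1]]]
    expect_identical(substring(fixed, 38, 38), unname(old))
    expect_identical(fixed, as.character(reads(fx$rs))[[1]])
    # and nothing else changed
    expect_identical(unname(as.character(records(ks))[names(seqs)[-1]]),
                     unname(seqs[-1]))
})

test_that("kspectrum is deterministic, never lengthens, stays on-alphabet", {
    fx <- tiny_fixture(L = 3000, het = 0.02, readLength = 60,
                       coverage = 30, errorRate = 0.03)
    a <- kspectrumCorrect(fx$rs, 13, 2)
    b <- kspectrumCorrect(fx$rs, 13, 2)
    expect_identical(as.character(records(a)), as.character(records(b)))
    expect_true(all(Biostrings::width(records(a)) ==
                    Biostrings::width(reads(fx$rs))))
    expect_false(any(grepl("[^ACGT]", as.character(records(a)))))
    expect_error(kspectrumCorrect(fx$rs, 60, 2), "31")
    short <- tiny_fixture(L = 500, readLength = 20, coverage = 4)
    expect_error(kspectrumCorrect(short$rs, 25, 2), "read length")
})

test_that("the canonical census pools a k-mer with its reverse complement", {
    fx <- tiny_fixture(L = 1000, het = 0, coverage = 6, errorRate = 0)
    census <- kmerCensus(fx$rs, 9)
    expect_false(any(duplicated(census$kmer)))
    rc <- vapply(census$kmer, revcomp_naive, character(1))
    # every stored k-mer is the lexicographic minimum of the pair
    expect_true(all(census$kmer <= rc))
    # total count equals the number of k-mer windows in the readset
    expect_equal(sum(census$count), sum(Biostrings::width(reads(fx$rs)) - 8))
})

test_that("external corrected FASTQ round-trips and flags mismatches", {
    fx <- tiny_fixture(errorRate = 0.03)
    fq <- tempfile(fileext = ".fastq"); tt <- tempfile(fileext = ".tsv")
    writeReadset(fx$rs, fq, tt)
    ext <- loadExternalCorrected(fq, fx$rs)
    expect_identical(unname(as.character(records(ext))[names(reads(fx$rs))]),
                     unname(as.character(reads(fx$rs))))
    expect_length(removedIds(ext, fx$rs), 0)

    # drop 3 reads -> 3 removed records
    lines <- readLines(fq)
    writeLines(lines[-(1:12)], fq)
    ext2 <- loadExternalCorrected(fq, fx$rs)
    expect_length(removedIds(ext2, fx$rs), 3)

    # a shortened read is accepted
    lines2 <- readLines(fq)
    lines2[2] <- substring(lines2[2], 3)
    lines2[4] <- substring(lines2[4], 3)
    writeLines(lines2, fq)
    ext3 <- loadExternalCorrected(fq, fx$rs)
    shortId <- sub("^@", "", lines2[1])
    expect_equal(Biostrings::width(records(ext3)[shortId]), 28)

    # unknown id is a hard error
    lines3 <- lines2
    lines3[1] <- "@not_a_read"
    writeLines(lines3, fq)
    expect_error(loadExternalCorrected(fq, fx$rs), "mismatch")

    # duplicate id is a hard error
    lines4 <- c(lines2, lines2[1:4])
    writeLines(lines4, fq)
    expect_error(loadExternalCorrected(fq, fx$rs), "duplicate")
    unlink(c(fq, tt))
})
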