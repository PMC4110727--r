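#' Configure a heterozygosity-by-error-rate sweep
#'
#' Builds a [SweepConfig-class]. The defaults reproduce the study design:
#' the 50-level heterozygosity grid ([hetGrid()]) crossed with four
#' substitution error rates (3.7\%, 4.6\%, 5.8\%, 7.3\%), 75 bp single-end
#' reads at 40x combined coverage, both dataset modes, giving 200 datasets
#' per corrector. The default demo genome is a 100 kb random reference —
#' long enough for a dense k-mer census, small enough to sweep on a
#' desktop; point \code{fastaPath} at a real reference to override.
#'
#' @param genomeLength Length of the random reference (ignored if
#'   \code{fastaPath} given).
#' @param fastaPath Optional FASTA supplying the reference (first record).
#' @param hetRates,errorRates The two grid axes.
#' @param readLength,coverage Read simulation parameters.
#' @param modes Dataset modes: \code{"heterozygous"} corrects the pooled
#'   readset; \code{"homozygous"} corrects the two haplotype halves
#'   independently and pools the evaluations.
#' @param correctors Named list mapping corrector name (one of
#'   \code{"oracle"}, \code{"identity"}, \code{"kspectrum"}, \code{"trim"},
#'   \code{"flip_markers"}) to its parameter list.
#' @param masterSeed Integer master seed; every configuration derives its
#'   own seed from it deterministically.
#' @param outputDir Optional directory for per-configuration TSVs.
#' @return A [SweepConfig-class].
#' @export
sweepConfig <- function(genomeLength = 100000L, fastaPath = NA_character_,
                        hetRates = hetGrid(),
                        errorRates = c(0.037, 0.046, 0.058, 0.073),
                        readLength = 75L, coverage = 40,
                        modes = c("heterozygous", "homozygous"),
                        correctors = list(kspectrum = list(k = 15L,
                                          trustThreshold = 2L)),
                        masterSeed = 1L, outputDir = NA_character_) {
    new("SweepConfig", genomeLength = as.integer(genomeLength),
        fastaPath = fastaPath, hetRates = hetRates, errorRates = errorRates,
        readLength = as.integer(readLength), coverage = coverage,
        modes = modes, correctors = correctors,
        masterSeed = as.integer(masterSeed), outputDir = outputDir)
}

setMethod("show", "SweepConfig", function(object) {
    cat("SweepConfig: ", length(object@hetRates), " het rates x ",
        length(object@errorRates), " error rates = ",
        length(object@hetRates) * length(object@errorRates),
        " configurations\n", sep = "")
    cat("  modes: ", paste(object@modes, collapse = ", "),
        "; correctors: ", paste(names(object@correctors), collapse = ", "),
        "\n", sep = "")
})

#' Enumerate the configurations of a sweep
#'
#' Cartesian product of the heterozygosity and error-rate grids, ordered by
#' heterozygosity ascending then error rate ascending, with each
#' configuration's derived simulation seed.
#'
#' @param cfg A [SweepConfig-class].
#' @return \code{data.frame} with columns \code{config_id},
#'   \code{het_rate}, \code{error_rate}, \code{seed}.
#' @examples
#' nrow(enumerateConfigs(sweepConfig()))   # 50 x 4 = 200
#' @export
enumerateConfigs <- function(cfg) {
    stopifnot(is(cfg, "SweepConfig"))
    het <- sort(cfg@hetRates)
    err <- sort(cfg@errorRates)
    grid <- expand.grid(error_rate = err, het_rate = het,
                        KEEP.OUT.ATTRS = FALSE)[, c("het_rate", "error_rate")]
    grid$config_id <- sprintf("het%.4f_err%.4f",
                              grid$het_rate, grid$error_rate)
    grid$seed <- mapply(function(h, e)
        derive_seed(cfg@masterSeed, h, e), grid$het_rate, grid$error_rate)
    rownames(grid) <- NULL
    grid[, c("config_id", "het_rate", "error_rate", "seed")]
}

# Resolve one configured corrector to a function(rs) -> CorrectedReadset.
resolve_corrector <- function(name, params, pair, seed) {
    switch(name,
        oracle   = function(rs) oracleCorrect(rs),
        identity = function(rs) identityCorrect(rs),
        trim     = function(rs) do.call(trimCorrect, c(list(rs), params)),
        kspectrum = function(rs)
            do.call(kspectrumCorrect, c(list(rs), params)),
        flip_markers = function(rs)
            do.call(flipMarkersCorrect,
                    c(list(rs, pair), params, list(seed = seed))),
        stop("unknown corrector: ", name))
}

# Sum two evaluation reports (used to pool the homozygous-mode halves).
combine_reports <- function(a, b) {
    stopifnot(identical(a@counts[, 1:3], b@counts[, 1:3]))
    cc <- a@counts
    cc$count <- cc$count + b@counts$count
    meta <- a@meta
    meta$n_reads <- a@meta$n_reads + b@meta$n_reads
    meta$n_events <- a@meta$n_events + b@meta$n_events
    new("EvaluationReport", counts = cc, meta = meta)
}

combine_chimera <- function(a, b) {
    new("ChimeraReport",
        nReadsTotal = a@nReadsTotal + b@nReadsTotal,
        nMultimarker = a@nMultimarker + b@nMultimarker,
        nChimeric = a@nChimeric + b@nChimeric,
        meta = a@meta)
}

#' Run one sweep configuration
#'
#' Simulates the diploid genome and readset for one (heterozygosity, error
#' rate) cell, then applies every configured corrector in every configured
#' mode. Heterozygous mode corrects the pooled readset; homozygous mode
#' splits the reads by source haplotype, corrects the two halves
#' independently, and pools the two evaluations.
#'
#' @param cfg A [SweepConfig-class].
#' @param hetRate,errorRate The cell to run.
#' @param refSeq Optional pre-built reference sequence (character or
#'   \code{DNAString}); by default a random reference of
#'   \code{cfg@genomeLength} derived from the master seed (shared across
#'   cells, as one source genome underlies the whole sweep).
#' @return Named list (one element per \code{mode.corrector}) of lists
#'   with elements \code{evaluation} ([EvaluationReport-class]) and
#'   \code{chimera} ([ChimeraReport-class]), plus attribute
#'   \code{"table"}: the long-format rows for aggregation.
#' @export
runConfig <- function(cfg, hetRate, errorRate, refSeq = NULL) {
    stopifnot(is(cfg, "SweepConfig"))
    if (is.null(refSeq)) {
        refSeq <- if (!is.na(cfg@fastaPath)) {
            seqs <- Biostrings::readDNAStringSet(cfg@fastaPath)
            as.character(seqs[[1]])
        } else as.character(
            randomReference(cfg@genomeLength,
                            seed = derive_seed(cfg@masterSeed, "genome")))
    }
    simSeed <- derive_seed(cfg@masterSeed, hetRate, errorRate)
    pair <- introduceHeterozygosity(refSeq, hetRate,
                                    seed = derive_seed(simSeed, "pair"))
    rs <- simulateReads(pair, readLength = cfg@readLength,
                        coverage = cfg@coverage, errorRate = errorRate,
                        seed = derive_seed(simSeed, "reads"))
    halves <- if ("homozygous" %in% cfg@modes) splitByHaplotype(rs)

    results <- list()
    rows <- list()
    for (cn in names(cfg@correctors)) {
        params <- cfg@correctors[[cn]]
        for (mode in cfg@modes) {
            fun <- resolve_corrector(cn, params, pair,
                                     derive_seed(simSeed, cn, mode))
            if (mode == "heterozygous") {
                corr <- fun(rs)
                evalRep <- evaluateCorrections(rs, pair, corr)
                chimRep <- chimeraReport(rs, pair, corr)
            } else {
                corrA <- fun(halves$A); corrB <- fun(halves$B)
                evalRep <- combine_reports(
                    evaluateCorrections(halves$A, pair, corrA),
                    evaluateCorrections(halves$B, pair, corrB))
                chimRep <- combine_chimera(
                    chimeraReport(halves$A, pair, corrA),
                    chimeraReport(halves$B, pair, corrB))
            }
            key <- paste(mode, cn, sep = ".")
            results[[key]] <- list(evaluation = evalRep, chimera = chimRep)
            tb <- as.data.frame(evalRep)
            tb$mode <- mode
            cb <- as.data.frame(chimRep)
            cb$mode <- mode
            cb$error_rate <- errorRate
            rows[[key]] <- list(base = tb, read = cb)
        }
    }
    attr(results, "table") <- list(
        base = do.call(rbind, lapply(rows, `[[`, "base")),
        read = do.call(rbind, lapply(rows, `[[`, "read")))
    results
}

#' Run a full sweep and collect the long-format results
#'
#' Iterates [runConfig()] over every cell of [enumerateConfigs()]. When
#' \code{cfg@outputDir} is set, writes \code{<config_id>_base.tsv} and
#' \code{<config_id>_read.tsv} per cell (re-loadable with
#' [aggregateReports()]). A failing cell is recorded and skipped; if any
#' cell failed the function raises an error at the end after returning
#' what completed via the condition's \code{data} field.
#'
#' @param cfg A [SweepConfig-class].
#' @param verbose Print one line per configuration.
#' @return List with \code{base} (base-level outcome table: one row per
#'   config x mode x corrector x stratum x outcome) and \code{read}
#'   (read-level chimera table: one row per config x mode x corrector).
#' @export
runSweep <- function(cfg, verbose = FALSE) {
    configs <- enumerateConfigs(cfg)
    refSeq <- if (!is.na(cfg@fastaPath)) {
        as.character(Biostrings::readDNAStringSet(cfg@fastaPath)[[1]])
    } else as.character(
        randomReference(cfg@genomeLength,
                        seed = derive_seed(cfg@masterSeed, "genome")))
    outDir <- cfg@outputDir
    if (!is.na(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    baseRows <- list(); readRows <- list(); failed <- character()
    for (i in seq_len(nrow(configs))) {
        ci <- configs[i, ]
        res <- tryCatch(
            runConfig(cfg, ci$het_rate, ci$error_rate, refSeq = refSeq),
            error = function(e) e)
        if (inherits(res, "error")) {
            warning("configuration ", ci$config_id, " failed: ",
                    conditionMessage(res))
            failed <- c(failed, ci$config_id)
            next
        }
        tab <- attr(res, "table")
        baseRows[[ci$config_id]] <- tab$base
        readRows[[ci$config_id]] <- tab$read
        if (!is.na(outDir)) {
            write.table(tab$base,
                        file.path(outDir, paste0(ci$config_id, "_base.tsv")),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            write.table(tab$read,
                        file.path(outDir, paste0(ci$config_id, "_read.tsv")),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        }
        if (verbose)
            message(sprintf("[%d/%d] %s done", i, nrow(configs),
                            ci$config_id))
    }
    out <- list(base = do.call(rbind, unname(baseRows)),
                read = do.call(rbind, unname(readRows)),
                failed = failed)
    if (length(failed))
        stop(length(failed), " configuration(s) failed: ",
             paste(failed, collapse = ", "))
    out
}

#' Aggregate per-configuration report files
#'
#' Reads every \code{*_base.tsv} and \code{*_read.tsv} a sweep wrote under
#' a directory and binds them into the two long-format tables. Re-running
#' on the same directory is idempotent.
#'
#' @param dir Directory written by [runSweep()].
#' @return List with \code{base} and \code{read} tables.
#' @export
aggregateReports <- function(dir) {
    bf <- sort(list.files(dir, pattern = "_base\\.tsv$", full.names = TRUE))
    rf <- sort(list.files(dir, pattern = "_read\\.tsv$", full.names = TRUE))
    if (!length(bf) && !length(rf))
        stop("no report files found under ", dir)
    rd <- function(f) read.delim(f, stringsAsFactors = FALSE)
    list(base = do.call(rbind, lapply(bf, rd)),
         read = do.call(rbind, lapply(rf, rd)))
}
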