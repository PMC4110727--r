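# Internal helpers shared across modules.

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(seed)
    }
    expr
}

# Complement of a vector of single bases (genome <-> read frame on '-').
complement_base <- function(x) {
    chartr("ACGT", "TGCA", x)
}

# Reverse-complement of a character vector of sequences.
revcomp_chr <- function(x) {
    if (!length(x)) return(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_dna <- function(x, what = "sequence") {
    bad <- grepl("[^ACGT]", x)
    if (any(bad))
        stop(what, " contains characters outside {A,C,G,T} ",
             "(ambiguity codes such as N are not supported)", call. = FALSE)
    invisible(x)
}

# Flat-index substitution on a vector of strings: set character at 1-based
# position `pos` of string `idx` to `value`. Vectorised via one big string.
substitute_chars <- function(seqs, idx, pos, value) {
    if (!length(idx)) return(seqs)
    lens <- nchar(seqs)
    off0 <- cumsum(c(0L, lens[-length(lens)]))
    ch <- strsplit(paste(seqs, collapse = ""), "")[[1]]
    ch[off0[idx] + pos] <- value
    big <- paste(ch, collapse = "")
    out <- substring(big, off0 + 1L, off0 + lens)
    names(out) <- names(seqs)
    out
}

# Hamming distance between equal-length string vectors, element-wise.
str_hamming <- function(a, b) {
    stopifnot(length(a) == length(b))
    if (!length(a)) return(integer())
    la <- nchar(a)
    stopifnot(all(la == nchar(b)))
    ra <- charToRaw(paste(a, collapse = ""))
    rb <- charToRaw(paste(b, collapse = ""))
    d <- as.integer(ra != rb)
    grp <- rep.int(seq_along(a), la)
    out <- integer(length(a))
    if (length(d)) {
        agg <- rowsum(d, grp)
        out[as.integer(rownames(agg))] <- as.integer(agg[, 1])
    }
    out
}

# Deterministic 31-bit seed from a vector of small components (integers or
# strings); order-sensitive mixing, always < 2^31.
derive_seed <- function(...) {
    parts <- list(...)
    acc <- 17
    for (p in parts) {
        v <- if (is.character(p)) utf8ToInt(paste(p, collapse = "|"))
             else round(as.numeric(p) * 1e6) %% 2147483647
        for (x in v) acc <- (acc * 131 + (x %% 65521) + 7) %% 2147483629
    }
    as.integer(acc)
}
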