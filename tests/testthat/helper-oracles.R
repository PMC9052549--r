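# Independent oracles and fixture builders shared across tests.

AA20 <- bmctyper:::AA20

# Exhaustive path-enumeration oracle for the forward score: sums the odds
# of every legal state path (entry into any match state, constant 0.1 exit
# from non-final match states) by direct recursion. Independent of the
# dynamic-programming implementation; tractable for profile length <= 3
# and query length <= 5.
oracleForwardBits <- function(prof, seq) {
    L <- profileLength(prof)
    si <- bmctyper:::aaIndex(seq)
    N <- length(si)
    mat <- prof@matchEmissions
    ins <- prof@insertEmissions
    bg <- prof@background
    tr <- prof@transitions
    pe <- function(k) if (k == L) 1 else 0.1
    emitOdds <- function(a, k) if (a < 0) 1 else mat[a + 1, k] / bg[a + 1]
    insOdds <- function(a) if (a < 0) 1 else ins[a + 1] / bg[a + 1]
    total <- 0
    rec <- function(type, k, i, w) {
        if (type == "M") {
            total <<- total + w * pe(k)
            if (k < L) {
                cont <- 1 - pe(k)
                if (i < N) rec("M", k + 1, i + 1,
                               w * cont * tr["mm", k] * emitOdds(si[i + 1], k + 1))
                if (i < N) rec("I", k, i + 1,
                               w * cont * tr["mi", k] * insOdds(si[i + 1]))
                rec("D", k + 1, i, w * cont * tr["md", k])
            }
        } else if (type == "I") {
            if (i < N) rec("M", k + 1, i + 1,
                           w * tr["im", k] * emitOdds(si[i + 1], k + 1))
            if (i < N) rec("I", k, i + 1, w * tr["ii", k] * insOdds(si[i + 1]))
        } else {
            if (k < L) {
                if (i < N) rec("M", k + 1, i + 1,
                               w * tr["dm", k] * emitOdds(si[i + 1], k + 1))
                rec("D", k + 1, i, w * tr["dd", k])
            }
        }
    }
    for (i in seq_len(N)) for (k in seq_len(L))
        rec("M", k, i, (1 / L) * emitOdds(si[i], k))
    unname(log2(total))
}

# Brute-force order component: maximum over both orientations and over all
# anchor pairings (i in f1 aligned to j in f2) of the aligned match count
# divided by max length. Coded independently of the offset loop used by
# the implementation.
oracleOrderComponent <- function(l1, l2) {
    denom <- max(length(l1), length(l2))
    best <- 0
    for (v2 in list(l2, rev(l2))) {
        for (i in seq_along(l1)) {
            for (j in seq_along(v2)) {
                off <- i - j
                idx <- seq_along(l1)
                ok <- idx - off >= 1 & idx - off <= length(v2)
                m <- sum(l1[ok] == v2[idx[ok] - off])
                best <- max(best, m / denom)
            }
        }
    }
    best
}

# Small random gapped alignments for oracle fixtures.
randomSmallMSA <- function(maxMatch = 3) {
    repeat {
        msa <- vapply(1:4, function(s) {
            n <- maxMatch + sample(0:2, 1)
            paste(sample(c(AA20, "-"), n, replace = TRUE,
                         prob = c(rep(0.045, 20), 0.1)), collapse = "")
        }, "")
        w <- max(nchar(msa))
        msa <- vapply(msa, function(x) paste0(x, strrep("-", w - nchar(x))), "")
        p <- try(buildProfile(msa, "X_oracle"), silent = TRUE)
        if (!inherits(p, "try-error") && profileLength(p) <= maxMatch)
            return(p)
    }
}

# A sharply informative motif profile (consensus bitscore far above the
# 20-bit default threshold) plus its training alignment.
makeMotifProfile <- function(name = "H_fix", motifLen = 40, nSeq = 4,
                             subRate = 0.05) {
    motif <- paste(sample(AA20, motifLen, replace = TRUE), collapse = "")
    msa <- vapply(seq_len(nSeq), function(s) {
        ch <- strsplit(motif, "")[[1]]
        hit <- runif(motifLen) < subRate
        if (any(hit)) ch[hit] <- sample(AA20, sum(hit), replace = TRUE)
        paste(ch, collapse = "")
    }, "")
    list(profile = buildProfile(msa, name), motif = motif, msa = msa)
}

# Sample a sequence along the profile consensus path (match emissions
# only) and shuffle residues of a sequence.
sampleProfileSeq <- function(profile) {
    em <- matchEmissions(profile)
    paste(vapply(seq_len(ncol(em)), function(k)
        sample(AA20, 1, prob = em[, k]), ""), collapse = "")
}

shuffleSeq <- function(seq) {
    paste(sample(strsplit(seq, "")[[1]]), collapse = "")
}

# Minimal HMMER3/f ASCII text for a profile given as probability matrices.
hmmer3Text <- function(name, matchEm, insertEm = rep(1 / 20, 20),
                       transRows = NULL, terminator = "//") {
    L <- ncol(matchEm)
    if (is.null(transRows))
        transRows <- matrix(c(0.8, 0.1, 0.1, 0.5, 0.5, 0.6, 0.4), 7, L)
    nl <- function(p) sprintf("%.5f", -log(p))
    lines <- c("HMMER3/f [3.4 | test]",
               paste0("NAME  ", name),
               paste0("LENG  ", L),
               "ALPH  amino",
               paste(c("HMM", AA20), collapse = "      "),
               "            m->m     m->i     m->d     i->m     i->i     d->m     d->d",
               paste(c("  COMPO", nl(rep(1 / 20, 20))), collapse = "  "),
               paste(c("       ", nl(insertEm)), collapse = "  "),
               paste(c("       ", nl(transRows[, 1])), collapse = "  "))
    for (k in seq_len(L)) {
        lines <- c(lines,
                   paste(c(sprintf("%7d", k), nl(matchEm[, k])), collapse = "  "),
                   paste(c("       ", nl(insertEm)), collapse = "  "),
                   paste(c("       ", nl(transRows[, k])), collapse = "  "))
    }
    c(lines, terminator)
}

locusToRecords <- function(locus) {
    data.frame(id = locus$id, description = "",
               index = seq_len(nrow(locus)) - 1L, seq = locus$seq,
               stringsAsFactors = FALSE)
}

# Shared small fixture world for the cheaper tests (built once per run).
smallWorld <- local({
    w <- NULL
    function() {
        if (is.null(w)) w <<- generateWorld(42, nTypes = 3, lociPerType = 2,
                                            locusLen = 12)
        w
    }
})
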