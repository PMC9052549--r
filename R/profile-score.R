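# Scoring sequences against profile HMMs with the built-in forward scorer.

# Constant per-match-state local exit probability (the last match state
# always exits). Documented model constant; see the methods vignette.
P_EXIT <- 0.1

.profileArgs <- function(profile) {
    list(matEm = profile@matchEmissions,
         insEm = profile@insertEmissions,
         trans = profile@transitions,
         bg = profile@background)
}

#' Forward-algorithm bitscore of a sequence against a profile
#'
#' Computes `log2(P(seq | profile) / P(seq | background))` by the forward
#' algorithm over a Plan7-style local alignment topology (uniform entry
#' into any match state, constant exit probability from each match state,
#' background-emitting flanks that cancel against the null model). The
#' computation is in log space and deterministic.
#'
#' @param profile A [ProfileHMM-class].
#' @param seq A protein sequence (non-standard letters score as
#'   background).
#' @return The bitscore (numeric scalar).
#' @seealso [scoreSequence()] for thresholded hits with envelopes,
#'   [viterbiScore()] for the single best path.
#' @export
forwardScore <- function(profile, seq) {
    si <- .checkSeq(seq)
    a <- .profileArgs(profile)
    .fwdBits(a$matEm, a$insEm, a$trans, a$bg, si, P_EXIT)
}

#' Viterbi (single best path) bitscore
#'
#' Same topology as [forwardScore()] but maximizing over paths instead of
#' summing; always less than or equal to the forward score.
#'
#' @inheritParams forwardScore
#' @return The Viterbi bitscore (numeric scalar).
#' @export
viterbiScore <- function(profile, seq) {
    si <- .checkSeq(seq)
    a <- .profileArgs(profile)
    .vitEnvelope(a$matEm, a$insEm, a$trans, a$bg, si, P_EXIT)[1]
}

.checkSeq <- function(seq) {
    if (!is.character(seq) || length(seq) != 1L || is.na(seq))
        stopInput("sequence must be a single string")
    if (nchar(seq) == 0L) stopInput("empty sequence")
    aaIndex(seq)
}

# Non-overlapping scoring envelopes: take the Viterbi envelope, then
# recurse into the flanking subsequences while they still pass the
# threshold on their own.
.findEnvelopes <- function(a, si, threshold) {
    rec <- function(lo, hi) {
        if (hi < lo) return(NULL)
        seg <- si[lo:hi]
        b <- .fwdBits(a$matEm, a$insEm, a$trans, a$bg, seg, P_EXIT)
        if (b < threshold) return(NULL)
        v <- .vitEnvelope(a$matEm, a$insEm, a$trans, a$bg, seg, P_EXIT)
        s <- lo + v[2] - 1L; e <- lo + v[3] - 1L
        rbind(rec(lo, s - 1L), c(s, e), rec(e + 1L, hi))
    }
    rec(1L, length(si))
}

#' Score one sequence against one profile
#'
#' Accepts the sequence when its forward bitscore reaches the acceptance
#' threshold and reports the scoring envelope(s): the Viterbi envelope plus
#' any flanking stretches that pass the threshold on their own (tandem
#' copies of a family, as in BMC-T proteins, yield `n_domains = 2`).
#'
#' @inheritParams forwardScore
#' @param threshold Acceptance threshold in bits; defaults to the
#'   profile's own threshold.
#' @param queryId Identifier copied into the hit.
#' @return A one-row hit `data.frame` (`query_id`, `profile_name`,
#'   `bitscore`, `env_start`, `env_end`, `n_domains`) or `NULL` when the
#'   score is below threshold.
#' @export
scoreSequence <- function(profile, seq, threshold = profileThreshold(profile),
                          queryId = NA_character_) {
    si <- .checkSeq(seq)
    a <- .profileArgs(profile)
    bits <- .fwdBits(a$matEm, a$insEm, a$trans, a$bg, si, P_EXIT)
    if (bits < threshold) return(NULL)
    env <- .findEnvelopes(a, si, threshold)
    data.frame(query_id = queryId, profile_name = profile@name,
               bitscore = bits, env_start = as.integer(min(env[, 1])),
               env_end = as.integer(max(env[, 2])),
               n_domains = nrow(env), stringsAsFactors = FALSE)
}

#' Search a profile library against ordered protein records
#'
#' Scores every protein against every profile and keeps hits at or above
#' the acceptance threshold. Output order follows input record order;
#' proteins without any accepted hit are present with an empty hit table.
#'
#' @param library A [ProfileLibrary-class] with at least one profile.
#' @param records Protein records as returned by [readMultiFasta()] (or a
#'   character vector of sequences, which will be given positional ids).
#' @param threshold Optional global threshold overriding the per-profile
#'   thresholds.
#' @return A named list (one element per protein, in input order) of hit
#'   data frames as in [scoreSequence()]; zero-row frames mark proteins
#'   with no accepted hit.
#' @export
searchLibrary <- function(library, records, threshold = NULL) {
    stopifnot(is(library, "ProfileLibrary"))
    if (length(library@profiles) == 0L)
        stopInput("profile library is empty")
    records <- .asRecords(records)
    if (nrow(records) == 0L) stopInput("empty record set")
    empty <- data.frame(query_id = character(), profile_name = character(),
                        bitscore = numeric(), env_start = integer(),
                        env_end = integer(), n_domains = integer(),
                        stringsAsFactors = FALSE)
    pargs <- lapply(library@profiles, .profileArgs)
    thr <- vapply(library@profiles, profileThreshold, 0)
    if (!is.null(threshold)) thr[] <- threshold
    cache <- new.env(parent = emptyenv())
    out <- lapply(seq_len(nrow(records)), function(i) {
        seq <- records$seq[i]
        key <- seq
        hits <- if (exists(key, envir = cache, inherits = FALSE)) cache[[key]] else {
            si <- aaIndex(seq)
            rows <- lapply(seq_along(pargs), function(j) {
                a <- pargs[[j]]
                bits <- .fwdBits(a$matEm, a$insEm, a$trans, a$bg, si, P_EXIT)
                if (bits < thr[j]) return(NULL)
                env <- .findEnvelopes(a, si, thr[j])
                data.frame(query_id = NA_character_,
                           profile_name = names(pargs)[j], bitscore = bits,
                           env_start = as.integer(min(env[, 1])),
                           env_end = as.integer(max(env[, 2])),
                           n_domains = nrow(env), stringsAsFactors = FALSE)
            })
            h <- do.call(rbind, c(list(empty), rows))
            cache[[key]] <- h
            h
        }
        if (nrow(hits)) hits$query_id <- records$id[i]
        hits
    })
    names(out) <- records$id
    out
}

.asRecords <- function(records) {
    if (is.character(records)) {
        records <- data.frame(id = sprintf("seq%03d", seq_along(records)),
                              description = "", index = seq_along(records) - 1L,
                              seq = records, stringsAsFactors = FALSE)
    }
    stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
    records
}
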