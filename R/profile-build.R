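# Building profile HMMs from multiple sequence alignments.

#' Build a profile HMM from a protein multiple alignment
#'
#' Match states are the alignment columns whose gap fraction is at most 0.5
#' (columns exactly at 0.5 are kept). Match emissions are observed residue
#' frequencies with a pseudocount of +1/20 per residue; insert emissions
#' pool the residues of all non-match columns with the same pseudocount.
#' Transitions are estimated from the gap structure of each row with +1
#' smoothing per transition. The result is deterministic and invariant to
#' the order of alignment rows.
#'
#' @param msa Aligned protein sequences: a character vector or
#'   `Biostrings::AAStringSet` of equal-length rows over the 20 standard
#'   amino acids plus gap (`-` or `.`); ambiguity letters are tolerated and
#'   ignored when counting.
#' @param name Profile name, ideally following the naming convention parsed
#'   by [classifyRole()].
#' @param role Functional role; defaults to the role parsed from `name`.
#' @param bmcType BMC type label, or `"generic"`; defaults to the type
#'   parsed from `name`.
#' @param background Null-model residue distribution (default uniform).
#' @param threshold Per-profile bitscore acceptance threshold (default 20).
#' @return A [ProfileHMM-class] object.
#' @examples
#' p <- buildProfile(c("ACDEF", "ACDEF", "ACDEF"), "H_demo")
#' profileLength(p)
#' @export
buildProfile <- function(msa, name, role = NULL, bmcType = NULL,
                         background = uniformBackground(), threshold = 20) {
    if (is(msa, "AAStringSet")) msa <- as.character(msa)
    if (!is.character(msa) || length(msa) == 0L)
        stopInput("empty alignment: at least one row is required")
    msa <- toupper(msa)
    widths <- nchar(msa)
    if (length(unique(widths)) != 1L)
        stopInput("ragged alignment: row %d has width %d, expected %d",
                  which(widths != widths[1])[1],
                  widths[which(widths != widths[1])[1]], widths[1])
    if (widths[1] == 0L) stopInput("alignment rows are empty")

    chars <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
    ok <- chars %in% c(AA20, AA_NONSTANDARD, GAP_CHARS)
    if (!all(ok)) {
        bad <- which(!matrix(ok, nrow(chars)), arr.ind = TRUE)[1, ]
        stopInput("invalid character '%s' in row %d, column %d",
                  chars[bad[1], bad[2]], bad[1], bad[2])
    }
    isGap <- matrix(chars %in% GAP_CHARS, nrow(chars))
    gapFrac <- colMeans(isGap)
    matchCols <- which(gapFrac <= 0.5)
    if (length(matchCols) == 0L)
        stopInput("no match columns: every column has gap fraction > 0.5")
    L <- length(matchCols)

    countResidues <- function(x) {
        tab <- table(factor(x[x %in% AA20], levels = AA20))
        as.numeric(tab)
    }
    matchEm <- vapply(matchCols, function(j) {
        cnt <- countResidues(chars[, j]) + 1 / 20
        cnt / sum(cnt)
    }, numeric(20))
    matchEm <- matrix(matchEm, nrow = 20,
                      dimnames = list(AA20, NULL))

    insCols <- setdiff(seq_len(ncol(chars)), matchCols)
    insCnt <- if (length(insCols)) countResidues(chars[, insCols]) else numeric(20)
    insCnt <- insCnt + 1 / 20
    insertEm <- setNames(insCnt / sum(insCnt), AA20)

    # Transition counts from each row's implied state path. Insert runs
    # between consecutive match columns are attributed to the left node;
    # Plan7 has no D->I or I->D, so inserts adjacent to a delete count
    # toward the delete's direct transition and the insert exit is counted
    # as I->M.
    trans <- matrix(1, nrow = 7, ncol = max(L - 1L, 0L),
                    dimnames = list(c("mm", "mi", "md", "im", "ii", "dm", "dd"),
                                    NULL))
    if (L > 1L) {
        cnt <- matrix(0, nrow = 7, ncol = L - 1L)
        for (r in seq_len(nrow(chars))) {
            isRes <- !isGap[r, matchCols]
            for (k in seq_len(L - 1L)) {
                between <- if (matchCols[k + 1L] - matchCols[k] > 1L) {
                    cols <- (matchCols[k] + 1L):(matchCols[k + 1L] - 1L)
                    sum(!isGap[r, cols])
                } else 0L
                from <- isRes[k]; to <- isRes[k + 1L]
                if (between > 0L && from) {
                    cnt[2, k] <- cnt[2, k] + 1          # M -> I
                    cnt[5, k] <- cnt[5, k] + between - 1 # I -> I
                    cnt[4, k] <- cnt[4, k] + 1          # I -> M (also toward D)
                } else if (from) {
                    if (to) cnt[1, k] <- cnt[1, k] + 1 else cnt[3, k] <- cnt[3, k] + 1
                } else {
                    if (to) cnt[6, k] <- cnt[6, k] + 1 else cnt[7, k] <- cnt[7, k] + 1
                }
            }
        }
        cnt <- cnt + 1  # +1 smoothing per transition
        trans[1:3, ] <- sweep(cnt[1:3, , drop = FALSE], 2,
                              colSums(cnt[1:3, , drop = FALSE]), "/")
        trans[4:5, ] <- sweep(cnt[4:5, , drop = FALSE], 2,
                              colSums(cnt[4:5, , drop = FALSE]), "/")
        trans[6:7, ] <- sweep(cnt[6:7, , drop = FALSE], 2,
                              colSums(cnt[6:7, , drop = FALSE]), "/")
    } else {
        trans <- trans[, 0, drop = FALSE]
    }

    parsed <- classifyRole(name)
    role <- role %||% parsed$role
    bmcType <- bmcType %||% (if (is.na(parsed$bmcType)) "generic" else parsed$bmcType)
    bg <- as.numeric(background)
    new("ProfileHMM", name = name, role = role, bmcType = bmcType,
        matchEmissions = matchEm, insertEmissions = insertEm,
        transitions = trans, background = setNames(bg / sum(bg), AA20),
        nTrain = length(msa), threshold = threshold)
}

#' Assemble profile HMMs into a library
#'
#' @param profileList List of [ProfileHMM-class] objects.
#' @param mode `"generic"` or `"type_specific"`; in type-specific mode every
#'   profile must carry a non-generic BMC type.
#' @return A [ProfileLibrary-class].
#' @export
profileLibrary <- function(profileList, mode = c("generic", "type_specific")) {
    mode <- match.arg(mode)
    if (!is.list(profileList)) profileList <- list(profileList)
    names(profileList) <- vapply(profileList, profileName, "")
    new("ProfileLibrary", profiles = profileList, mode = mode)
}
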