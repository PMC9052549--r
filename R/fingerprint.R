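# Locus fingerprints, inventory+order similarity, ranking, clustering, and
# the majority-vote type call.

#' Build a locus fingerprint from ordered best assignments
#'
#' The fingerprint is the ordered list of best-hit profile names, one per
#' protein with an accepted hit, in gene order. Proteins with role `NONE`
#' are excluded.
#'
#' @param assignments Best-assignment data frame ([assignBest()]), in locus
#'   order.
#' @param locusId Identifier for the locus.
#' @return A [Fingerprint-class].
#' @export
makeFingerprint <- function(assignments, locusId) {
    keep <- assignments$role != "NONE"
    if (!any(keep)) stopEmpty("nothing to fingerprint: no assigned proteins")
    new("Fingerprint", locusId = locusId,
        labels = assignments$profile_name[keep])
}

#' Fingerprint from a character vector of labels
#'
#' Convenience constructor used when the labels are already known (e.g.
#' registry entries, fixture truth).
#'
#' @param labels Ordered profile names.
#' @param locusId Locus identifier.
#' @return A [Fingerprint-class].
#' @export
fingerprint <- function(labels, locusId = "locus") {
    new("Fingerprint", locusId = locusId, labels = as.character(labels))
}

#' Inventory + order similarity between two locus fingerprints
#'
#' The correlation score blends two components: the Jaccard index of the
#' label sets (component inventory) and an order component, the maximum
#' over all integer offsets -- and over both orientations, since operons
#' occur on either strand -- of the count of aligned positions with equal
#' labels divided by `max(length(f1), length(f2))`. The blended value is
#' `alpha * inventory + (1 - alpha) * order`; it is symmetric, bounded in
#' `[0, 1]`, and equals 1 on identical non-empty fingerprints.
#'
#' @param f1,f2 [Fingerprint-class] objects (non-empty).
#' @param alpha Blending weight for the inventory component (default 0.5).
#' @param orientations `"both"` (default) searches the reversed orientation
#'   of `f2` as well; `"forward"` disables the reversal search.
#' @return A [SimilarityScore-class].
#' @examples
#' a <- fingerprint(c("A", "B", "C")); b <- fingerprint(c("C", "B", "A"))
#' similarityValue(fingerprintSimilarity(a, b))            # 1
#' similarityValue(fingerprintSimilarity(a, b, orientations = "forward"))
#' @export
fingerprintSimilarity <- function(f1, f2, alpha = 0.5,
                                  orientations = c("both", "forward")) {
    orientations <- match.arg(orientations)
    l1 <- fingerprintLabels(f1); l2 <- fingerprintLabels(f2)
    if (length(l1) == 0L || length(l2) == 0L)
        stopInput("cannot compare empty fingerprints")
    inv <- length(intersect(l1, l2)) / length(union(l1, l2))
    n1 <- length(l1); n2 <- length(l2)
    denom <- max(n1, n2)
    bestFrac <- 0; bestOff <- 0L; bestOri <- "forward"
    for (ori in c("forward", if (orientations == "both") "reversed")) {
        v2 <- if (ori == "forward") l2 else rev(l2)
        for (off in seq(-(n2 - 1L), n1 - 1L)) {
            i <- seq(max(1L, 1L + off), min(n1, n2 + off))
            if (length(i) == 0L) next
            frac <- sum(l1[i] == v2[i - off]) / denom
            if (frac > bestFrac) {
                bestFrac <- frac; bestOff <- as.integer(off); bestOri <- ori
            }
        }
    }
    new("SimilarityScore",
        value = alpha * inv + (1 - alpha) * bestFrac,
        inventory = inv, order = bestFrac, bestOffset = bestOff,
        orientation = bestOri, alpha = alpha)
}

#' Rank the closest BMC types for a fingerprint
#'
#' Scores the fingerprint against every example fingerprint of every
#' registry type, keeps each type's best-matching example, and returns the
#' top `k` types by similarity (ties broken by lexicographic type label).
#'
#' @param f A [Fingerprint-class].
#' @param registry A [TypeRegistry-class] (non-empty).
#' @param k Number of entries to report (default 5, the closest-types
#'   report length).
#' @param alpha Blending weight passed to [fingerprintSimilarity()].
#' @return A `data.frame` with columns `rank`, `type`, `value`,
#'   `inventory`, `order`, `offset`, `orientation`;
#'   `min(k, number of types)` rows, value non-increasing.
#' @export
rankClosest <- function(f, registry, k = 5L, alpha = 0.5) {
    stopifnot(is(registry, "TypeRegistry"))
    entries <- registry@entries
    if (length(entries) == 0L) stopInput("empty type registry")
    rows <- lapply(entries, function(e) {
        scores <- lapply(e$fingerprints, fingerprintSimilarity, f1 = f,
                         alpha = alpha)
        best <- scores[[which.max(vapply(scores, slot, 0, "value"))]]
        data.frame(type = e$type_id, value = best@value,
                   inventory = best@inventory, order = best@order,
                   offset = best@bestOffset, orientation = best@orientation,
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(-tab$value, tab$type), , drop = FALSE]
    tab <- head(tab, k)
    tab <- cbind(rank = seq_len(nrow(tab)), tab)
    rownames(tab) <- NULL
    tab
}

#' Single-linkage clustering of locus fingerprints
#'
#' Computes all pairwise similarities and returns the connected components
#' of the graph with edges wherever similarity >= `threshold`
#' (single-linkage). Cluster labels are ordered by the lexicographically
#' smallest member locus id.
#'
#' @param fingerprints List of [Fingerprint-class] objects (>= 1).
#' @param threshold Similarity threshold for joining (default 0.6).
#' @param alpha Blending weight passed to [fingerprintSimilarity()].
#' @return A `data.frame` with columns `locus_id` and `cluster` (integer
#'   labels starting at 1).
#' @export
clusterLoci <- function(fingerprints, threshold = 0.6, alpha = 0.5) {
    stopifnot(length(fingerprints) >= 1L)
    ids <- vapply(fingerprints, locusId, "")
    n <- length(fingerprints)
    if (n == 1L) return(data.frame(locus_id = ids, cluster = 1L,
                                   stringsAsFactors = FALSE))
    sim <- matrix(1, n, n)
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            s <- fingerprintSimilarity(fingerprints[[i]], fingerprints[[j]],
                                       alpha = alpha)@value
            sim[i, j] <- sim[j, i] <- s
        }
    }
    h <- 1 - threshold + 1e-12  # inclusive joining at similarity == threshold
    if (h < 0) {
        memb <- seq_len(n)
    } else {
        hc <- hclust(as.dist(1 - sim), method = "single")
        memb <- cutree(hc, h = h)
    }
    # relabel by smallest member locus id
    mins <- vapply(split(ids, memb), min, "")
    newLab <- order(order(mins))  # rank of each cluster's smallest member id
    data.frame(locus_id = ids,
               cluster = as.integer(newLab[match(memb, as.integer(names(mins)))]),
               stringsAsFactors = FALSE)
}

#' Call the BMC type of a locus by majority vote
#'
#' Every typed assignment votes for its BMC type. A unique modal type with
#' `modal count / total votes >= majority` yields status `assigned`;
#' otherwise the call is `ambiguous` (the mixed-type pattern of candidate
#' novel loci), with the modal fraction as confidence. A locus without any
#' shell-role assignment is `no_shell`. The BMC types of any
#' signature-enzyme assignments are carried along as a functional hint for
#' ambiguous calls.
#'
#' @param assignments Best-assignment data frame from a type-specific
#'   library ([assignBest()]).
#' @param majority Majority threshold (default 0.5).
#' @param shellOnly If `TRUE`, only shell-role assignments vote.
#' @return A [TypeAssignment-class].
#' @examples
#' # a six-way one-vote-each split is ambiguous with confidence 1/6
#' @export
callType <- function(assignments, majority = 0.5, shellOnly = FALSE) {
    emptyVotes <- setNames(integer(0), character(0))
    sigTypes <- unique(assignments$bmc_type[
        assignments$role == "SIGNATURE_ENZYME" & !is.na(assignments$bmc_type)])
    if (!any(assignments$is_shell)) {
        return(new("TypeAssignment", bmcType = NA_character_, confidence = 0,
                   status = "no_shell", voteTable = emptyVotes,
                   signatureTypes = character(0)))
    }
    pool <- if (shellOnly) assignments[assignments$is_shell, , drop = FALSE]
            else assignments
    votes <- pool$bmc_type[!is.na(pool$bmc_type)]
    if (length(votes) == 0L) {
        return(new("TypeAssignment", bmcType = NA_character_, confidence = 0,
                   status = "ambiguous", voteTable = emptyVotes,
                   signatureTypes = sigTypes))
    }
    tab <- table(votes)
    tab <- tab[order(-as.integer(tab), names(tab))]
    tabInt <- setNames(as.integer(tab), names(tab))
    modal <- unname(tabInt[1])
    conf <- modal / sum(tabInt)
    uniqueModal <- sum(tabInt == modal) == 1L
    if (uniqueModal && conf >= majority) {
        new("TypeAssignment", bmcType = names(tabInt)[1], confidence = conf,
            status = "assigned", voteTable = tabInt,
            signatureTypes = sigTypes)
    } else {
        new("TypeAssignment", bmcType = NA_character_, confidence = conf,
            status = "ambiguous", voteTable = tabInt,
            signatureTypes = sigTypes)
    }
}
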