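# S4 classes for the central data objects.

#' ProfileHMM: a position-specific model of one protein family
#'
#' A profile hidden Markov model over the 20 standard amino acids with
#' match, insert and delete states. Emissions and transitions are stored as
#' probabilities (strictly positive after pseudocounting). Each profile is
#' tagged with a functional role and a BMC type ("generic" for profiles not
#' trained on a single type), following the `<TYPE>__<ROLE>_<color>` naming
#' convention (see [classifyRole()]).
#'
#' @slot name Profile name.
#' @slot role One of [bmcRoles()].
#' @slot bmcType BMC type label, or `"generic"`.
#' @slot matchEmissions 20 x L matrix; column k is the emission
#'   distribution of match state k (rows in order `ACDEFGHIKLMNPQRSTVWY`).
#' @slot insertEmissions length-20 insert emission distribution, shared
#'   across insert states.
#' @slot transitions 7 x (L-1) matrix of per-state transition probabilities,
#'   rows `mm, mi, md, im, ii, dm, dd` (state k to state k+1).
#' @slot background length-20 null-model distribution.
#' @slot nTrain number of training sequences.
#' @slot threshold per-profile bitscore acceptance threshold.
#' @exportClass ProfileHMM
setClass("ProfileHMM",
    representation(name = "character", role = "character",
                   bmcType = "character", matchEmissions = "matrix",
                   insertEmissions = "numeric", transitions = "matrix",
                   background = "numeric", nTrain = "integer",
                   threshold = "numeric"))

setValidity("ProfileHMM", function(object) {
    tol <- 1e-9
    L <- ncol(object@matchEmissions)
    if (L < 1L) return("profile must have at least one match state")
    if (nrow(object@matchEmissions) != 20L)
        return("matchEmissions must have 20 rows")
    if (length(object@insertEmissions) != 20L ||
        length(object@background) != 20L)
        return("insertEmissions and background must have length 20")
    if (any(object@matchEmissions <= 0) || any(object@insertEmissions <= 0) ||
        any(object@background <= 0))
        return("all emission probabilities must be strictly positive")
    if (any(abs(colSums(object@matchEmissions) - 1) > tol))
        return("match emission columns must sum to 1")
    if (abs(sum(object@insertEmissions) - 1) > tol)
        return("insert emissions must sum to 1")
    if (abs(sum(object@background) - 1) > tol)
        return("background must sum to 1")
    tr <- object@transitions
    if (nrow(tr) != 7L) return("transitions must have 7 rows")
    if (ncol(tr) != L - 1L)
        return("transitions must have length(profile) - 1 columns")
    if (L > 1L) {
        if (any(tr <= 0)) return("all transition probabilities must be strictly positive")
        grp <- rbind(colSums(tr[1:3, , drop = FALSE]),
                     colSums(tr[4:5, , drop = FALSE]),
                     colSums(tr[6:7, , drop = FALSE]))
        if (any(abs(grp - 1) > tol))
            return("each state's outgoing transition group must sum to 1")
    }
    if (!object@role %in% ROLE_LEVELS) return("unknown role")
    TRUE
})

#' ProfileLibrary: a named collection of profile HMMs
#'
#' @slot profiles named list of [ProfileHMM-class] objects (names unique).
#' @slot mode `"generic"` (shell-class level profiles) or
#'   `"type_specific"` (every profile trained on a single BMC type).
#' @exportClass ProfileLibrary
setClass("ProfileLibrary",
    representation(profiles = "list", mode = "character"))

setValidity("ProfileLibrary", function(object) {
    nms <- names(object@profiles)
    if (length(object@profiles) &&
        (is.null(nms) || anyDuplicated(nms) || any(!nzchar(nms))))
        return("profile names must be unique and non-empty")
    for (p in object@profiles) {
        if (!is(p, "ProfileHMM")) return("profiles must be ProfileHMM objects")
    }
    if (!identical(unname(vapply(object@profiles, slot, "", "name")),
                   unname(nms)))
        return("list names must equal profile names")
    if (!object@mode %in% c("generic", "type_specific"))
        return("mode must be 'generic' or 'type_specific'")
    if (object@mode == "type_specific") {
        ty <- vapply(object@profiles, slot, "", "bmcType")
        if (any(ty == "generic" | is.na(ty)))
            return("type_specific libraries require a BMC type on every profile")
    }
    TRUE
})

#' Fingerprint: the ordered profile labels of one locus
#'
#' The unit of locus comparison: the names of the best-scoring profiles of
#' a locus, one per protein with an accepted hit, in gene order.
#'
#' @slot locusId locus identifier.
#' @slot labels ordered character vector of profile names.
#' @exportClass Fingerprint
setClass("Fingerprint",
    representation(locusId = "character", labels = "character"))

setValidity("Fingerprint", function(object) {
    if (length(object@locusId) != 1L || !nzchar(object@locusId))
        return("locusId must be a single non-empty string")
    if (length(object@labels) < 1L)
        return("fingerprint labels must be non-empty")
    TRUE
})

#' TypeAssignment: the called BMC type of a locus
#'
#' @slot bmcType called type, or `NA` when not assigned.
#' @slot confidence modal vote fraction in `[0, 1]`.
#' @slot status `"assigned"`, `"ambiguous"` or `"no_shell"`.
#' @slot voteTable named integer vector of votes per type, sorted by
#'   decreasing count then type label.
#' @slot signatureTypes BMC types of any signature-enzyme assignments
#'   (reported separately as a hint when the call is ambiguous).
#' @exportClass TypeAssignment
setClass("TypeAssignment",
    representation(bmcType = "character", confidence = "numeric",
                   status = "character", voteTable = "integer",
                   signatureTypes = "character"))

setValidity("TypeAssignment", function(object) {
    if (!object@status %in% c("assigned", "ambiguous", "no_shell"))
        return("status must be assigned, ambiguous or no_shell")
    if (object@confidence < 0 || object@confidence > 1)
        return("confidence must be in [0, 1]")
    if (object@status == "assigned" && is.na(object@bmcType))
        return("assigned calls must carry a type")
    TRUE
})

#' SimilarityScore: blended inventory/order similarity of two fingerprints
#'
#' @slot value blended similarity `alpha * inventory + (1 - alpha) * order`.
#' @slot inventory Jaccard index of the label sets.
#' @slot order best offset/orientation-maximized label-match fraction.
#' @slot bestOffset integer offset achieving the order component.
#' @slot orientation `"forward"` or `"reversed"`.
#' @slot alpha blending weight used.
#' @exportClass SimilarityScore
setClass("SimilarityScore",
    representation(value = "numeric", inventory = "numeric",
                   order = "numeric", bestOffset = "integer",
                   orientation = "character", alpha = "numeric"))

#' CandidateLocus: a window of genes around shell-protein hits
#'
#' @slot records protein record data frame slice (see [readMultiFasta()]).
#' @slot anchorIndices 0-based proteome indices of the shell hits that
#'   seeded the locus.
#' @slot window genes on each side used for extraction.
#' @slot start,end 0-based inclusive proteome indices of the slice.
#' @exportClass CandidateLocus
setClass("CandidateLocus",
    representation(records = "data.frame", anchorIndices = "integer",
                   window = "integer", start = "integer", end = "integer"))

setValidity("CandidateLocus", function(object) {
    if (length(object@anchorIndices) < 1L)
        return("anchorIndices must be non-empty")
    if (any(object@anchorIndices < object@start |
            object@anchorIndices > object@end))
        return("anchors must lie within the locus slice")
    if (nrow(object@records) != object@end - object@start + 1L)
        return("records slice must match [start, end]")
    TRUE
})

#' TypeRegistry: packaged registry of BMC types with example fingerprints
#'
#' @slot entries named list; each entry is a list with elements `type_id`,
#'   `description`, `fingerprints` (list of [Fingerprint-class]),
#'   `inventory` (character) and `sequences` (named character, possibly
#'   empty).
#' @exportClass TypeRegistry
setClass("TypeRegistry", representation(entries = "list"))

setValidity("TypeRegistry", function(object) {
    ids <- names(object@entries)
    if (length(object@entries) == 0L) return("registry must not be empty")
    if (is.null(ids) || anyDuplicated(ids)) return("type ids must be unique")
    for (e in object@entries) {
        if (length(e$fingerprints) < 1L)
            return(sprintf("type '%s' has no example fingerprint", e$type_id))
    }
    TRUE
})

#' FixtureWorld: a seeded synthetic test universe
#'
#' Deterministic toy protein families, training alignments and labeled loci
#' used to exercise the whole pipeline without downloads (see
#' [generateWorld()]).
#'
#' @slot seed integer seed the world was generated from.
#' @slot types synthetic BMC type labels.
#' @slot families named list of families, one per (type, role): elements
#'   `name`, `type`, `role`, `stem`, `motif`, `msa` (character vector of
#'   equal-length training/held-out sequences).
#' @slot loci named list of locus data frames (columns `id`, `seq`,
#'   `role_truth`, `family`, `type_truth`).
#' @slot params generation parameters.
#' @exportClass FixtureWorld
setClass("FixtureWorld",
    representation(seed = "integer", types = "character", families = "list",
                   loci = "list", params = "list"))
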