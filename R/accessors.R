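# Accessor generics and show methods.

#' Accessors for bmctyper S4 objects
#'
#' Small accessor functions in place of direct slot access.
#'
#' @param x An object of the matching class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("profileName", function(x) standardGeneric("profileName"))
#' @rdname accessors
#' @export
setMethod("profileName", "ProfileHMM", function(x) x@name)

#' @rdname accessors
#' @export
setGeneric("profileRole", function(x) standardGeneric("profileRole"))
#' @rdname accessors
#' @export
setMethod("profileRole", "ProfileHMM", function(x) x@role)

#' @rdname accessors
#' @export
setGeneric("profileType", function(x) standardGeneric("profileType"))
#' @rdname accessors
#' @export
setMethod("profileType", "ProfileHMM", function(x) x@bmcType)

#' @rdname accessors
#' @export
setGeneric("profileLength", function(x) standardGeneric("profileLength"))
#' @rdname accessors
#' @export
setMethod("profileLength", "ProfileHMM", function(x) ncol(x@matchEmissions))

#' @rdname accessors
#' @export
setGeneric("profileThreshold", function(x) standardGeneric("profileThreshold"))
#' @rdname accessors
#' @export
setMethod("profileThreshold", "ProfileHMM", function(x) x@threshold)

#' @rdname accessors
#' @export
setGeneric("matchEmissions", function(x) standardGeneric("matchEmissions"))
#' @rdname accessors
#' @export
setMethod("matchEmissions", "ProfileHMM", function(x) x@matchEmissions)

#' @rdname accessors
#' @export
setGeneric("consensusSequence", function(x) standardGeneric("consensusSequence"))
#' @rdname accessors
#' @export
setMethod("consensusSequence", "ProfileHMM", function(x) {
    paste(AA20[apply(x@matchEmissions, 2L, which.max)], collapse = "")
})

#' @rdname accessors
#' @export
setGeneric("libraryMode", function(x) standardGeneric("libraryMode"))
#' @rdname accessors
#' @export
setMethod("libraryMode", "ProfileLibrary", function(x) x@mode)

#' @rdname accessors
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))
#' @rdname accessors
#' @export
setMethod("profiles", "ProfileLibrary", function(x) x@profiles)

#' @rdname accessors
#' @export
setMethod("length", "ProfileLibrary", function(x) length(x@profiles))

#' @rdname accessors
#' @param i Profile name or index.
#' @export
setMethod("[[", "ProfileLibrary", function(x, i) x@profiles[[i]])

#' @rdname accessors
#' @export
setGeneric("locusId", function(x) standardGeneric("locusId"))
#' @rdname accessors
#' @export
setMethod("locusId", "Fingerprint", function(x) x@locusId)

#' @rdname accessors
#' @export
setGeneric("fingerprintLabels", function(x) standardGeneric("fingerprintLabels"))
#' @rdname accessors
#' @export
setMethod("fingerprintLabels", "Fingerprint", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("length", "Fingerprint", function(x) length(x@labels))

#' @rdname accessors
#' @export
setGeneric("assignedType", function(x) standardGeneric("assignedType"))
#' @rdname accessors
#' @export
setMethod("assignedType", "TypeAssignment", function(x) x@bmcType)

#' @rdname accessors
#' @export
setGeneric("confidence", function(x) standardGeneric("confidence"))
#' @rdname accessors
#' @export
setMethod("confidence", "TypeAssignment", function(x) x@confidence)

#' @rdname accessors
#' @export
setGeneric("typingStatus", function(x) standardGeneric("typingStatus"))
#' @rdname accessors
#' @export
setMethod("typingStatus", "TypeAssignment", function(x) x@status)

#' @rdname accessors
#' @export
setGeneric("voteTable", function(x) standardGeneric("voteTable"))
#' @rdname accessors
#' @export
setMethod("voteTable", "TypeAssignment", function(x) x@voteTable)

#' @rdname accessors
#' @export
setGeneric("signatureTypes", function(x) standardGeneric("signatureTypes"))
#' @rdname accessors
#' @export
setMethod("signatureTypes", "TypeAssignment", function(x) x@signatureTypes)

#' @rdname accessors
#' @export
setGeneric("similarityValue", function(x) standardGeneric("similarityValue"))
#' @rdname accessors
#' @export
setMethod("similarityValue", "SimilarityScore", function(x) x@value)

#' @rdname accessors
#' @export
setGeneric("locusRecords", function(x) standardGeneric("locusRecords"))
#' @rdname accessors
#' @export
setMethod("locusRecords", "CandidateLocus", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("anchorIndices", function(x) standardGeneric("anchorIndices"))
#' @rdname accessors
#' @export
setMethod("anchorIndices", "CandidateLocus", function(x) x@anchorIndices)

#' @rdname accessors
#' @export
setGeneric("registryEntries", function(x) standardGeneric("registryEntries"))
#' @rdname accessors
#' @export
setMethod("registryEntries", "TypeRegistry", function(x) x@entries)

#' @rdname accessors
#' @export
setMethod("length", "TypeRegistry", function(x) length(x@entries))

#' @rdname accessors
#' @export
setGeneric("worldTypes", function(x) standardGeneric("worldTypes"))
#' @rdname accessors
#' @export
setMethod("worldTypes", "FixtureWorld", function(x) x@types)

#' @rdname accessors
#' @export
setGeneric("worldFamilies", function(x) standardGeneric("worldFamilies"))
#' @rdname accessors
#' @export
setMethod("worldFamilies", "FixtureWorld", function(x) x@families)

#' @rdname accessors
#' @export
setGeneric("worldLoci", function(x) standardGeneric("worldLoci"))
#' @rdname accessors
#' @export
setMethod("worldLoci", "FixtureWorld", function(x) x@loci)

setMethod("show", "ProfileHMM", function(object) {
    cat(sprintf("ProfileHMM '%s' (role %s, type %s): %d match states, %d training seqs\n",
                object@name, object@role, object@bmcType,
                ncol(object@matchEmissions), object@nTrain))
})

setMethod("show", "ProfileLibrary", function(object) {
    cat(sprintf("ProfileLibrary (%s): %d profiles\n", object@mode,
                length(object@profiles)))
    if (length(object@profiles)) {
        nm <- names(object@profiles)
        cat("  ", paste(head(nm, 6), collapse = ", "),
            if (length(nm) > 6) ", ..." else "", "\n", sep = "")
    }
})

setMethod("show", "Fingerprint", function(object) {
    cat(sprintf("Fingerprint '%s' (%d labels): %s\n", object@locusId,
                length(object@labels),
                paste(head(object@labels, 8), collapse = " > ")))
})

setMethod("show", "TypeAssignment", function(object) {
    cat(sprintf("TypeAssignment: %s (status %s, confidence %.3f)\n",
                ifelse(is.na(object@bmcType), "<none>", object@bmcType),
                object@status, object@confidence))
    if (length(object@voteTable))
        cat("  votes:", paste(sprintf("%s=%d", names(object@voteTable),
                                      object@voteTable), collapse = " "), "\n")
})

setMethod("show", "SimilarityScore", function(object) {
    cat(sprintf("SimilarityScore %.4f (inventory %.4f, order %.4f, offset %d, %s)\n",
                object@value, object@inventory, object@order,
                object@bestOffset, object@orientation))
})

setMethod("show", "CandidateLocus", function(object) {
    cat(sprintf("CandidateLocus [%d, %d] (%d genes, %d anchors, window %d)\n",
                object@start, object@end, nrow(object@records),
                length(object@anchorIndices), object@window))
})

setMethod("show", "TypeRegistry", function(object) {
    cat(sprintf("TypeRegistry: %d types\n", length(object@entries)))
})

setMethod("show", "FixtureWorld", function(object) {
    cat(sprintf("FixtureWorld (seed %d): %d types, %d families, %d loci\n",
                object@seed, length(object@types), length(object@families),
                length(object@loci)))
})
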