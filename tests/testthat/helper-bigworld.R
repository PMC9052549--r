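# The reference study-condition world (seed 1, 10 types, 8 loci per type)
# shared by the recovery and corruption suites; built once per test run.

bigWorldData <- local({
    dat <- NULL
    function() {
        if (is.null(dat)) {
            w <- generateWorld(1, nTypes = 10, lociPerType = 8,
                               locusLen = 20)
            dat <<- list(world = w, lib = worldProfileLibrary(w),
                         registry = worldRegistry(w))
        }
        dat
    }
})

# Batch-classify a list of locus data frames with one shared scoring pass
# over the unique sequences.
classifyLoci <- function(loci, lib, majority = 0.5) {
    allSeqs <- unique(unlist(lapply(loci, `[[`, "seq"), use.names = FALSE))
    recs <- data.frame(id = sprintf("u%05d", seq_along(allSeqs)),
                       description = "", index = seq_along(allSeqs) - 1L,
                       seq = allSeqs, stringsAsFactors = FALSE)
    bySeq <- assignBest(searchLibrary(lib, recs))
    lapply(loci, function(locus) {
        asg <- bySeq[match(locus$seq, allSeqs), , drop = FALSE]
        asg$query_id <- locus$id
        callType(asg, majority = majority)
    })
}
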