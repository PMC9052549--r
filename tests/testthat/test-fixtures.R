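test_that("fixture worlds regenerate bit-identically from the same seed", {
    w1 <- generateWorld(5, nTypes = 2, lociPerType = 1, locusLen = 10)
    w2 <- generateWorld(5, nTypes = 2, lociPerType = 1, locusLen = 10)
    expect_identical(worldFamilies(w1), worldFamilies(w2))
    expect_identical(worldLoci(w1), worldLoci(w2))
    expect_length(worldLoci(w1), 2L)
    w3 <- generateWorld(6, nTypes = 2, lociPerType = 1, locusLen = 10)
    expect_false(identical(worldLoci(w1), worldLoci(w3)))
})

test_that("world generation does not disturb the caller's RNG stream", {
    set.seed(999)
    a <- runif(1)
    set.seed(999)
    invisible(generateWorld(3, nTypes = 2, lociPerType = 1))
    expect_identical(runif(1), a)
})

test_that("generated worlds satisfy their structural invariants", {
    w <- smallWorld()
    expect_true(all(vapply(worldFamilies(w),
                           function(f) length(f$msa) >= 3L, TRUE)))
    for (locus in worldLoci(w)) {
        expect_true(any(locus$role_truth %in% shellRoles()))
        expect_true(all(locus$type_truth[!is.na(locus$family)] %in%
                        worldTypes(w)))
    }
    expect_error(generateWorld(1, nTypes = 1), "nTypes",
                 class = "bmc_input_error")
    expect_error(generateWorld(1, familySize = 2), "familySize",
                 class = "bmc_input_error")
})

test_that("corruption modes behave as designed", {
    w <- smallWorld()
    lib <- worldProfileLibrary(w)
    locus <- worldLoci(w)[[1]]
    # shuffle: same vote table (voting is order-free)
    sh <- corruptLocus(locus, "shuffle", seed = 3)
    asgO <- assignBest(searchLibrary(lib, locusToRecords(locus)))
    asgS <- assignBest(searchLibrary(lib, locusToRecords(sh)))
    expect_equal(voteTable(callType(asgS)), voteTable(callType(asgO)))
    # drop_shell: no shell genes remain
    dr <- corruptLocus(locus, "drop_shell", seed = 3)
    expect_false(any(dr$role_truth %in% shellRoles()))
    asgD <- assignBest(searchLibrary(lib, locusToRecords(dr)))
    expect_equal(typingStatus(callType(asgD)), "no_shell")
    # mix_types: no type keeps a majority
    mx <- corruptLocus(locus, "mix_types", seed = 3, world = w)
    asgM <- assignBest(searchLibrary(lib, locusToRecords(mx)))
    expect_equal(typingStatus(callType(asgM)), "ambiguous")
    # determinism per seed
    expect_identical(corruptLocus(locus, "mix_types", seed = 3, world = w),
                     mx)
})

test_that("worlds written to disk are consumable by the other modules", {
    w <- smallWorld()
    dir <- tempfile()
    writeWorld(w, dir)
    expect_true(file.exists(file.path(dir, "truth.tsv")))
    lid <- names(worldLoci(w))[1]
    recs <- readMultiFasta(file.path(dir, "loci", paste0(lid, ".faa")))
    expect_equal(recs$seq, worldLoci(w)[[lid]]$seq)
    reg <- loadRegistry(file.path(dir, "world.registry"))
    expect_equal(length(reg), length(worldTypes(w)))
    fam <- worldFamilies(w)[[1]]
    msa <- readMultiFasta(file.path(dir, "families",
                                    paste0(fam$name, ".afa")))
    expect_equal(msa$seq, fam$msa)
})

test_that("held-out loci recover their true type on a small world", {
    w <- smallWorld()
    ev <- evaluateTypeRecovery(w)
    expect_true(all(ev$status == "assigned"))
    expect_true(all(ev$called == ev$type_truth))
    expect_true(all(ev$rank1_correct))
})
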