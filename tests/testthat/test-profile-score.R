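test_that("forward DP equals exhaustive path enumeration on small fixtures", {
    set.seed(101)
    checked <- 0
    while (checked < 25) {
        p <- randomSmallMSA(maxMatch = 3)
        q <- paste(sample(AA20, sample(1:5, 1), replace = TRUE),
                   collapse = "")
        dp <- forwardScore(p, q)
        oracle <- oracleForwardBits(p, q)
        expect_equal(dp, oracle, tolerance = 1e-9)
        checked <- checked + 1
    }
})

test_that("forward score dominates the Viterbi score", {
    set.seed(102)
    for (i in 1:10) {
        p <- randomSmallMSA(maxMatch = 3)
        q <- paste(sample(AA20, sample(2:6, 1), replace = TRUE),
                   collapse = "")
        expect_gte(forwardScore(p, q), viterbiScore(p, q) - 1e-12)
    }
})

test_that("consensus of a sharply peaked profile scores positive", {
    set.seed(103)
    fix <- makeMotifProfile("H_sharp", motifLen = 12, subRate = 0)
    expect_gt(forwardScore(fix$profile, consensusSequence(fix$profile)), 0)
})

test_that("profile-sampled sequences outscore their shuffles on average", {
    set.seed(104)
    fix <- makeMotifProfile("H_samp", motifLen = 30)
    p <- fix$profile
    seqs <- vapply(1:50, function(i) sampleProfileSeq(p), "")
    real <- vapply(seqs, function(s) forwardScore(p, s), 0)
    shuf <- vapply(seqs, function(s) forwardScore(p, shuffleSeq(s)), 0)
    expect_gt(mean(real), mean(shuf))
})

test_that("empty and invalid sequences are rejected", {
    p <- buildProfile(c("ACDEF", "ACDEF", "ACDEF"), "H_e")
    expect_error(forwardScore(p, ""), "empty", class = "bmc_input_error")
    expect_error(scoreSequence(p, ""), "empty", class = "bmc_input_error")
})

test_that("non-standard residues score as background", {
    p <- buildProfile(c("ACDEF", "ACDEF", "ACDEF"), "H_ns")
    # X contributes zero log-odds, so it scores below the consensus letter
    expect_lt(forwardScore(p, "ACXEF"), forwardScore(p, "ACDEF"))
    expect_true(is.finite(forwardScore(p, "XXXXX")))
})

test_that("scoreSequence thresholds and reports envelopes", {
    set.seed(105)
    fix <- makeMotifProfile("H_env", motifLen = 40, subRate = 0.02)
    p <- fix$profile
    cons <- consensusSequence(p)
    hit <- scoreSequence(p, cons, queryId = "q1")
    expect_equal(hit$query_id, "q1")
    expect_equal(hit$n_domains, 1L)
    expect_true(hit$env_start >= 1 && hit$env_end <= nchar(cons))
    # random sequence: no hit at the default 20-bit threshold
    expect_null(scoreSequence(p, shuffleSeq(cons)))
    # tandem construct: two copies of the consensus -> two envelopes
    tandem <- scoreSequence(p, paste0(cons, cons))
    expect_equal(tandem$n_domains, 2L)
    expect_gt(tandem$env_end, nchar(cons))
})

test_that("searchLibrary preserves order and keeps empty hit lists", {
    set.seed(106)
    fixA <- makeMotifProfile("SYNA__H_one", motifLen = 40)
    fixB <- makeMotifProfile("SYNB__P_two", motifLen = 40)
    lib <- profileLibrary(list(fixA$profile, fixB$profile),
                          mode = "type_specific")
    consA <- consensusSequence(fixA$profile)
    recs <- data.frame(id = c("hitA", "nohit"), description = "",
                       index = 0:1, seq = c(consA, shuffleSeq(consA)),
                       stringsAsFactors = FALSE)
    hits <- searchLibrary(lib, recs)
    expect_equal(names(hits), c("hitA", "nohit"))
    expect_equal(hits[["hitA"]]$profile_name, "SYNA__H_one")
    expect_equal(nrow(hits[["nohit"]]), 0L)
    expect_error(searchLibrary(profileLibrary(list(), "generic"), recs),
                 "empty", class = "bmc_input_error")
    expect_error(searchLibrary(lib, recs[0, ]), "empty record",
                 class = "bmc_input_error")
})
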