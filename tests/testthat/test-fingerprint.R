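asgRow <- function(id, name, bits = 30) {
    parsed <- classifyRole(name)
    data.frame(query_id = id, profile_name = name, role = parsed$role,
               bmc_type = parsed$bmcType, bitscore = bits,
               is_shell = parsed$role %in% shellRoles(),
               n_domains = 1L, stringsAsFactors = FALSE)
}

noneRow <- function(id) {
    data.frame(query_id = id, profile_name = NA_character_, role = "NONE",
               bmc_type = NA_character_, bitscore = NA_real_,
               is_shell = FALSE, n_domains = NA_integer_,
               stringsAsFactors = FALSE)
}

test_that("fingerprints keep assigned labels in gene order", {
    asg <- rbind(asgRow("g1", "H_azure"), noneRow("g2"),
                 asgRow("g3", "P_amber"))
    fp <- makeFingerprint(asg, "loc1")
    expect_equal(fingerprintLabels(fp), c("H_azure", "P_amber"))
    expect_equal(locusId(fp), "loc1")
    expect_error(makeFingerprint(rbind(noneRow("g1"), noneRow("g2")), "x"),
                 "nothing to fingerprint", class = "bmc_empty_error")
})

test_that("similarity blends inventory and offset/orientation order", {
    a <- fingerprint(c("A", "B", "C"), "a")
    self <- fingerprintSimilarity(a, a)
    expect_equal(self@value, 1)
    expect_equal(self@bestOffset, 0L)
    expect_equal(self@orientation, "forward")
    # disjoint inventories score zero
    d <- fingerprintSimilarity(a, fingerprint(c("X", "Y"), "d"))
    expect_equal(d@value, 0)
    # reversed operon: perfect with orientation search, 2/3 without
    b <- fingerprint(c("C", "B", "A"), "b")
    expect_equal(fingerprintSimilarity(a, b)@value, 1)
    expect_equal(fingerprintSimilarity(a, b, orientations = "forward")@value,
                 0.5 * 1 + 0.5 * (1 / 3))
})

test_that("similarity is symmetric, bounded, and matches the brute-force
           offset/orientation oracle", {
    set.seed(110)
    pool <- c("H_a", "H_b", "P_c", "Ts_d", "SIG_e", "ALDDH_f")
    for (i in 1:60) {
        l1 <- sample(pool, sample(1:6, 1), replace = TRUE)
        l2 <- sample(pool, sample(1:6, 1), replace = TRUE)
        s12 <- fingerprintSimilarity(fingerprint(l1), fingerprint(l2))
        s21 <- fingerprintSimilarity(fingerprint(l2), fingerprint(l1))
        expect_equal(s12@value, s21@value, tolerance = 1e-12)
        expect_gte(s12@value, 0); expect_lte(s12@value, 1)
        expect_equal(s12@order, oracleOrderComponent(l1, l2),
                     tolerance = 1e-12)
    }
})

test_that("rankClosest returns the best five types in order", {
    reg <- new("TypeRegistry", entries = setNames(lapply(1:7, function(i) {
        list(type_id = sprintf("T%02d", i), description = "",
             fingerprints = list(fingerprint(c(sprintf("T%02d__H_x", i),
                                               "H_shared")[seq_len(i %% 2 + 1)],
                                             sprintf("T%02d_ex", i))),
             inventory = character(0), sequences = character(0))
    }), sprintf("T%02d", 1:7)))
    # a fingerprint identical to T03's example ranks T03 first with value 1
    f <- fingerprint(fingerprintLabels(reg@entries[["T03"]]$fingerprints[[1]]),
                     "query")
    top <- rankClosest(f, reg)
    expect_equal(nrow(top), 5L)
    expect_equal(top$type[1], "T03")
    expect_equal(top$value[1], 1)
    expect_true(all(diff(top$value) <= 1e-12))
    # k larger than the registry returns every type
    expect_equal(nrow(rankClosest(f, reg, k = 99)), 7L)
    # first element dominates a full scan
    all7 <- rankClosest(f, reg, k = 7)
    expect_equal(top$value[1], max(all7$value))
})

test_that("single-linkage clustering respects the similarity threshold", {
    f1 <- fingerprint(c("A", "B", "C"), "locA")
    f2 <- fingerprint(c("A", "B", "C"), "locB")
    f3 <- fingerprint(c("X", "Y"), "locC")
    cl <- clusterLoci(list(f1, f2, f3), threshold = 0.6)
    expect_equal(cl$cluster, c(1L, 1L, 2L))
    expect_equal(max(clusterLoci(list(f1, f2, f3), threshold = 0)$cluster), 1L)
    expect_equal(clusterLoci(list(f1, f2, f3), threshold = 1.5)$cluster,
                 1:3)
})

test_that("majority voting assigns, detects ambiguity, and flags no_shell", {
    # the six-way one-vote-each mixed pattern of a candidate novel type
    six <- do.call(rbind, lapply(seq_along(c("SPU5", "ACI", "SPU4", "SPU1",
                                             "EUT2D", "SPU6")), function(i) {
        ty <- c("SPU5", "ACI", "SPU4", "SPU1", "EUT2D", "SPU6")[i]
        asgRow(sprintf("g%d", i), sprintf("%s__H_c%d", ty, i))
    }))
    tc <- callType(six)
    expect_equal(typingStatus(tc), "ambiguous")
    expect_equal(confidence(tc), 1 / 6)
    expect_true(is.na(assignedType(tc)))
    # unanimous vote
    all8 <- do.call(rbind, lapply(1:8, function(i)
        asgRow(sprintf("g%d", i), sprintf("PDU1A__H_c%d", i))))
    tc8 <- callType(all8)
    expect_equal(typingStatus(tc8), "assigned")
    expect_equal(assignedType(tc8), "PDU1A")
    expect_equal(confidence(tc8), 1)
    # 3:2 split passes the 0.5 majority with a unique mode
    asg32 <- rbind(asgRow("g1", "X__H_a"), asgRow("g2", "X__P_b"),
                   asgRow("g3", "X__Ts_c"), asgRow("g4", "Y__H_d"),
                   asgRow("g5", "Y__P_e"))
    tc32 <- callType(asg32)
    expect_equal(assignedType(tc32), "X")
    expect_equal(confidence(tc32), 0.6)
    # votes are a multiset: permutation invariance and exact counts
    perm <- asg32[sample(5), ]
    tcp <- callType(perm)
    expect_equal(voteTable(tcp), voteTable(tc32))
    expect_equal(confidence(tcp) * sum(voteTable(tcp)),
                 max(voteTable(tcp)))
    # no shell assignment at all -> no_shell
    enzOnly <- rbind(asgRow("g1", "X__SIG_a"), asgRow("g2", "X__ALDDH_b"))
    expect_equal(typingStatus(callType(enzOnly)), "no_shell")
    # signature-enzyme hint accompanies ambiguous calls
    mix <- rbind(asgRow("g1", "X__H_a"), asgRow("g2", "Y__H_b"),
                 asgRow("g3", "SPU9__SIG_c"))
    tcm <- callType(mix)
    expect_equal(typingStatus(tcm), "ambiguous")
    expect_equal(signatureTypes(tcm), "SPU9")
})
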