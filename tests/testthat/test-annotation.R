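test_that("profile names parse to role and type", {
    expect_equal(classifyRole("SPU1__H_azure"),
                 list(role = "BMC_H", bmcType = "SPU1"))
    expect_equal(classifyRole("P_amber"),
                 list(role = "BMC_P", bmcType = NA_character_))
    expect_equal(classifyRole("frobnicator"),
                 list(role = "OTHER_CONSERVED", bmcType = NA_character_))
    expect_equal(classifyRole("Hp_coral")$role, "BMC_Hp")
    expect_equal(classifyRole("EUT2D__ALDDH_rust"),
                 list(role = "ALDDH", bmcType = "EUT2D"))
})

test_that("the role color map matches the locus diagram scheme", {
    cols <- roleColors()
    expect_equal(unname(cols["BMC_P"]), "yellow")
    expect_equal(unname(cols[c("BMC_H", "BMC_Hp")]), c("blue", "blue"))
    expect_equal(unname(cols[c("BMC_Ts", "BMC_Tsp")]),
                 c("lightblue", "lightblue"))
    expect_equal(unname(cols["BMC_Tdp"]), "teal")
    expect_equal(unname(cols["SIGNATURE_ENZYME"]), "purple")
    expect_equal(unname(cols["REGULATOR"]), "orange")
    expect_equal(unname(cols["ALDDH"]), "red")
    expect_equal(unname(cols["ALCDH"]), "green")
    expect_equal(unname(cols["PTAC"]), "magenta")
    expect_equal(unname(cols["OTHER_CONSERVED"]), "black")
    expect_equal(unname(cols["NONE"]), "grey")
})

test_that("assignBest keeps the top hit with deterministic tie-breaking", {
    hit <- function(name, bits) data.frame(query_id = "q", profile_name = name,
        bitscore = bits, env_start = 1L, env_end = 10L, n_domains = 1L,
        stringsAsFactors = FALSE)
    hits <- list(q = rbind(hit("X_red", 55.0), hit("Y_blue", 41.2)))
    expect_equal(assignBest(hits)$profile_name, "X_red")
    # exact tie -> lexicographically smallest profile name
    tie <- list(q = rbind(hit("B_red", 30.0), hit("A_red", 30.0)))
    expect_equal(assignBest(tie)$profile_name, "A_red")
    # permutation of the hit rows does not change the winner
    tie2 <- list(q = rbind(hit("A_red", 30.0), hit("B_red", 30.0)))
    expect_equal(assignBest(tie2), assignBest(tie))
    # no hits -> role NONE
    none <- assignBest(list(q = hit("x", 1)[0, ]))
    expect_equal(none$role, "NONE")
    expect_true(is.na(none$profile_name))
    expect_false(none$is_shell)
    expect_equal(nrow(assignBest(list())), 0L)
})

test_that("shell-only scan finds planted shell proteins and counts them", {
    set.seed(108)
    fixH <- makeMotifProfile("SYNA__H_one", motifLen = 40)
    fixP <- makeMotifProfile("SYNA__P_twocol", motifLen = 40)
    lib <- profileLibrary(list(fixH$profile, fixP$profile),
                          mode = "type_specific")
    bystanders <- vapply(1:20, function(i)
        paste(sample(AA20, 45, replace = TRUE), collapse = ""), "")
    seqs <- c(bystanders[1:10], consensusSequence(fixH$profile),
              bystanders[11:20], consensusSequence(fixP$profile))
    recs <- data.frame(id = sprintf("p%02d", seq_along(seqs)),
                       description = "", index = seq_along(seqs) - 1L,
                       seq = seqs, stringsAsFactors = FALSE)
    scan <- scanShellOnly(recs, lib)
    expect_equal(nrow(scan$assignments), 2L)
    expect_equal(scan$assignments$query_id, c("p11", "p22"))
    expect_equal(unname(scan$summary[c("BMC_H", "BMC_P")]), c(1L, 1L))
    expect_equal(sum(scan$summary), nrow(scan$assignments))
    # a proteome without shell proteins gives an empty, all-zero summary
    scan0 <- scanShellOnly(recs[1:5, ], lib)
    expect_equal(nrow(scan0$assignments), 0L)
    expect_equal(sum(scan0$summary), 0L)
})

test_that("shell-only scan rejects libraries with non-shell profiles", {
    set.seed(109)
    enz <- makeMotifProfile("SYNA__SIG_enz", motifLen = 30)
    lib <- profileLibrary(list(enz$profile), mode = "type_specific")
    recs <- data.frame(id = "p1", description = "", index = 0L,
                       seq = "MKVLLAACDEF", stringsAsFactors = FALSE)
    expect_error(scanShellOnly(recs, lib), "shell",
                 class = "bmc_input_error")
})
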