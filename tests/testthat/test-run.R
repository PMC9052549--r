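# End-to-end runs of the pipeline driver and its artifacts.

setupRunFixture <- local({
    fix <- NULL
    function() {
        if (!is.null(fix)) return(fix)
        w <- smallWorld()
        dir <- tempfile("runfix")
        dir.create(dir)
        libPath <- file.path(dir, "profiles.library")
        writeProfileLibrary(worldProfileLibrary(w), libPath)
        regPath <- file.path(dir, "world.registry")
        saveRegistry(worldRegistry(w), regPath)
        lid <- names(worldLoci(w))[1]
        locusFa <- file.path(dir, "locus.faa")
        writeMultiFasta(locusToRecords(worldLoci(w)[[lid]]), locusFa)
        proteome <- do.call(rbind, lapply(worldLoci(w)[1:2], locusToRecords))
        proteome$index <- seq_len(nrow(proteome)) - 1L
        protFa <- file.path(dir, "proteome.faa")
        writeMultiFasta(proteome, protFa)
        fix <<- list(world = w, dir = dir, libPath = libPath,
                     regPath = regPath, locusFa = locusFa, protFa = protFa,
                     lid = lid)
        fix
    }
})

test_that("call-locus writes its four artifacts and matches fixture truth", {
    fx <- setupRunFixture()
    out <- file.path(fx$dir, "call1")
    res <- runAnalysis("call-locus", input = fx$locusFa,
                       libraryPath = fx$libPath, registryPath = fx$regPath,
                       outputDir = out)
    for (f in c("assignments.tsv", "type_call.tsv", "closest_types.tsv",
                "locus.svg", "locus.html", "manifest.json"))
        expect_true(file.exists(file.path(out, f)), label = f)
    truthType <- worldLoci(fx$world)[[fx$lid]]$type_truth[1]
    expect_equal(assignedType(res$typeCall), truthType)
    expect_equal(res$closest$type[1], truthType)
    tab <- utils::read.delim(file.path(out, "type_call.tsv"))
    expect_equal(tab$type, truthType)
    expect_equal(tab$status, "assigned")
})

test_that("scan-proteome records the default window in its manifest", {
    fx <- setupRunFixture()
    out <- file.path(fx$dir, "scan1")
    res <- runAnalysis("scan-proteome", input = fx$protFa,
                       libraryPath = fx$libPath, outputDir = out)
    m <- jsonlite::read_json(file.path(out, "manifest.json"),
                             simplifyVector = TRUE)
    expect_equal(m$parameters$window, 12L)
    expect_equal(m$mode, "scan-proteome")
    expect_true(file.exists(file.path(out, "candidate_loci.tsv")))
    expect_gt(nrow(res$scan$assignments), 0L)
})

test_that("a proteome without shell hits yields an empty interval list", {
    fx <- setupRunFixture()
    none <- tempfile(fileext = ".faa")
    set.seed(112)
    writeMultiFasta(data.frame(id = sprintf("r%02d", 1:10),
                               seq = vapply(1:10, function(i)
                                   paste(sample(AA20, 50, TRUE),
                                         collapse = ""), "")), none)
    out <- tempfile()
    res <- runAnalysis("scan-proteome", input = none,
                       libraryPath = fx$libPath, outputDir = out)
    expect_length(res$loci, 0L)
    expect_equal(nrow(utils::read.delim(file.path(out,
                                                  "candidate_loci.tsv"))), 0L)
})

test_that("repeated runs produce byte-identical TSV and SVG artifacts", {
    fx <- setupRunFixture()
    outA <- file.path(fx$dir, "detA"); outB <- file.path(fx$dir, "detB")
    for (o in c(outA, outB))
        runAnalysis("call-locus", input = fx$locusFa,
                    libraryPath = fx$libPath, registryPath = fx$regPath,
                    outputDir = o)
    for (f in c("assignments.tsv", "type_call.tsv", "closest_types.tsv",
                "locus.svg"))
        expect_identical(readLines(file.path(outA, f)),
                         readLines(file.path(outB, f)), label = f)
})

test_that("missing inputs fail with classed input errors", {
    fx <- setupRunFixture()
    expect_error(runAnalysis("call-locus", input = "does_not_exist.faa",
                             libraryPath = fx$libPath,
                             outputDir = tempfile()),
                 class = "bmc_input_error")
    expect_error(runAnalysis("call-locus", input = fx$locusFa,
                             libraryPath = "missing.library",
                             outputDir = tempfile()),
                 class = "bmc_input_error")
})

test_that("build-profiles mode builds a library from aligned FASTA files", {
    fx <- setupRunFixture()
    fam <- worldFamilies(fx$world)[[1]]
    msaDir <- tempfile(); dir.create(msaDir)
    msaPath <- file.path(msaDir, paste0(fam$name, ".afa"))
    writeMultiFasta(data.frame(id = paste0("s", seq_along(fam$msa)),
                               seq = fam$msa), msaPath)
    out <- tempfile()
    res <- runAnalysis("build-profiles", input = msaPath, outputDir = out)
    expect_true(file.exists(file.path(out, "profiles.library")))
    lib <- readProfileLibrary(file.path(out, "profiles.library"))
    expect_equal(names(profiles(lib)), fam$name)
    expect_equal(libraryMode(lib), "type_specific")
})

test_that("db and simulate modes emit their artifacts", {
    out <- tempfile()
    res <- runAnalysis("db", outputDir = out)
    tab <- utils::read.delim(file.path(out, "types.tsv"))
    expect_equal(nrow(tab), 68L)
    out2 <- tempfile()
    runAnalysis("simulate", outputDir = out2, seed = 9,
                worldParams = list(nTypes = 2, lociPerType = 1,
                                   locusLen = 8))
    expect_true(file.exists(file.path(out2, "truth.tsv")))
    expect_true(file.exists(file.path(out2, "world.registry")))
})
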