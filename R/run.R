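# Pipeline runner behind the command-line interface: executes one analysis
# mode, writes its artifacts and a machine-readable run manifest.

.writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

.manifest <- function(outputDir, mode, params, inputPaths, outputs) {
    sums <- character(0)
    for (p in inputPaths) {
        if (!is.null(p) && file.exists(p))
            sums[p] <- unname(tools::md5sum(p))
    }
    m <- list(tool = "bmctyper",
              version = as.character(utils::packageVersion("bmctyper")),
              mode = mode, parameters = params,
              input_md5 = as.list(sums), outputs = outputs)
    jsonlite::write_json(m, file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    m
}

.typeCallRow <- function(tc) {
    votes <- voteTable(tc)
    data.frame(type = ifelse(is.na(assignedType(tc)), "none",
                             assignedType(tc)),
               confidence = confidence(tc), status = typingStatus(tc),
               votes = paste(sprintf("%s:%d", names(votes), votes),
                             collapse = ";"),
               signature_types = paste(signatureTypes(tc), collapse = ";"),
               stringsAsFactors = FALSE)
}

#' Run one analysis mode end to end
#'
#' The programmatic core of the command-line tool. Executes one of the
#' analysis modes and writes its artifacts plus a `manifest.json`
#' recording the effective parameters and input checksums into
#' `outputDir`. Modes:
#' \describe{
#'   \item{call-locus}{full locus analysis of an ordered multi-FASTA:
#'     assignment TSV, type-call report, closest-types report, and
#'     SVG/HTML locus diagram.}
#'   \item{scan-proteome}{shell-protein-only scan: shell assignment TSV,
#'     per-class summary, candidate-locus intervals (1-based in the
#'     report); with `chain = TRUE` each candidate locus is then analyzed
#'     as in call-locus into a subdirectory.}
#'   \item{closest}{closest-types report only.}
#'   \item{build-profiles}{builds a profile library from aligned FASTA
#'     files (one profile per file, named after the file).}
#'   \item{db}{writes the type listing of the registry.}
#'   \item{simulate}{writes a seeded [generateWorld()] fixture world.}
#'   \item{render}{locus diagram only.}
#' }
#' Rejections signal classed conditions which the CLI maps to exit codes
#' (2 input error, 3 empty/degenerate analysis, 4 internal).
#'
#' @param mode Analysis mode (see above).
#' @param input Input path(s): multi-FASTA for the analysis modes, aligned
#'   FASTA files for `build-profiles`.
#' @param libraryPath Path to a native profile library
#'   ([writeProfileLibrary()]) or HMMER3 ASCII file.
#' @param registryPath Registry path (default: the shipped registry).
#' @param outputDir Output directory (created if needed).
#' @param window Genes on each side for candidate loci (default 12).
#' @param k Closest-types report length (default 5).
#' @param alpha Inventory/order blending weight (default 0.5).
#' @param majority Majority-vote threshold (default 0.5).
#' @param threshold Optional global bitscore threshold (default: each
#'   profile's own, 20 unless overridden).
#' @param layout Diagram layout, `"cascading"` (default) or `"linear"`.
#' @param seed Integer seed (used by `simulate`).
#' @param chain In `scan-proteome`, analyze each candidate locus too.
#' @param shellOnlyVotes Restrict type votes to shell assignments.
#' @param worldParams Named list of [generateWorld()] arguments for
#'   `simulate`.
#' @param verbose Emit timestamped progress messages to standard error.
#' @return Invisibly, a list of the run's in-memory results (including the
#'   manifest).
#' @export
runAnalysis <- function(mode = c("call-locus", "scan-proteome", "closest",
                                 "build-profiles", "db", "simulate",
                                 "render"),
                        input = NULL, libraryPath = NULL,
                        registryPath = NULL, outputDir,
                        window = 12L, k = 5L, alpha = 0.5, majority = 0.5,
                        threshold = NULL, layout = "cascading", seed = 1L,
                        chain = FALSE, shellOnlyVotes = FALSE,
                        worldParams = list(), verbose = FALSE) {
    mode <- match.arg(mode)
    log <- function(...) if (verbose)
        message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    params <- list(window = as.integer(window), k = as.integer(k),
                   alpha = alpha, majority = majority,
                   threshold = threshold %||% "per-profile",
                   layout = layout, seed = as.integer(seed),
                   chain = chain, shell_only_votes = shellOnlyVotes)
    loadLib <- function() {
        if (is.null(libraryPath)) stopInput("a profile library is required")
        if (!file.exists(libraryPath))
            stopInput("library file not found: '%s'", libraryPath)
        first <- readLines(libraryPath, n = 1L)
        if (grepl("^HMMER3", first)) importHMMER3(libraryPath)
        else readProfileLibrary(libraryPath)
    }
    loadReg <- function() loadRegistry(registryPath %||% defaultRegistryPath())

    result <- list()
    outputs <- character(0)

    if (mode %in% c("call-locus", "closest", "render")) {
        records <- readMultiFasta(input)
        lib <- loadLib()
        log("scoring %d proteins against %d profiles", nrow(records),
            length(lib))
        hits <- searchLibrary(lib, records, threshold = threshold)
        asg <- assignBest(hits)
        tc <- callType(asg, majority = majority, shellOnly = shellOnlyVotes)
        if (!any(asg$role != "NONE"))
            stopEmpty("no profile matches in the input locus")
        fp <- makeFingerprint(asg, locusId = "query_locus")
        result$assignments <- asg
        result$typeCall <- tc
        if (mode %in% c("call-locus", "closest")) {
            reg <- loadReg()
            closest <- rankClosest(fp, reg, k = k, alpha = alpha)
            result$closest <- closest
            outputs <- c(outputs,
                         .writeTSV(closest, file.path(outputDir,
                                                      "closest_types.tsv")))
        }
        if (mode %in% c("call-locus", "render")) {
            svg <- renderLocus(records, asg, tc, layout = layout)
            writeLines(svg, file.path(outputDir, "locus.svg"))
            outputs <- c(outputs, file.path(outputDir, "locus.svg"))
        }
        if (mode == "call-locus") {
            outputs <- c(outputs,
                .writeTSV(asg, file.path(outputDir, "assignments.tsv")),
                .writeTSV(.typeCallRow(tc), file.path(outputDir,
                                                      "type_call.tsv")))
            html <- renderLocusHTML(records, asg, tc,
                                    closest = result$closest,
                                    layout = layout)
            writeLines(html, file.path(outputDir, "locus.html"))
            outputs <- c(outputs, file.path(outputDir, "locus.html"))
        }
        inputPaths <- c(input, libraryPath,
                        if (mode != "render") registryPath %||%
                            defaultRegistryPath())
    } else if (mode == "scan-proteome") {
        records <- readMultiFasta(input)
        lib <- loadLib()
        shellNames <- names(Filter(function(p) roleIsShell(profileRole(p)),
                                   lib@profiles))
        shellLib <- profileLibrary(lib@profiles[shellNames],
                                   mode = lib@mode)
        if (length(shellLib) == 0L)
            stopInput("library contains no shell-protein profiles")
        log("shell scan of %d proteins with %d shell profiles",
            nrow(records), length(shellLib))
        scan <- scanShellOnly(records, shellLib, threshold = threshold)
        result$scan <- scan
        hitIdx <- records$index[match(scan$assignments$query_id, records$id)]
        loci <- extractNeighborhoods(records, hitIdx, window = window)
        result$loci <- loci
        intervals <- if (length(loci)) do.call(rbind, lapply(loci, function(l)
            data.frame(start = l@start + 1L, end = l@end + 1L,
                       n_genes = nrow(l@records),
                       anchors = paste(l@anchorIndices + 1L, collapse = ";"),
                       stringsAsFactors = FALSE)))
        else data.frame(start = integer(), end = integer(),
                        n_genes = integer(), anchors = character(),
                        stringsAsFactors = FALSE)
        outputs <- c(outputs,
            .writeTSV(scan$assignments,
                      file.path(outputDir, "shell_assignments.tsv")),
            .writeTSV(data.frame(shell_class = names(scan$summary),
                                 count = unname(scan$summary),
                                 stringsAsFactors = FALSE),
                      file.path(outputDir, "shell_summary.tsv")),
            .writeTSV(intervals, file.path(outputDir, "candidate_loci.tsv")))
        if (chain && length(loci)) {
            for (i in seq_along(loci)) {
                sub <- file.path(outputDir, sprintf("locus_%02d", i))
                subFa <- file.path(outputDir,
                                   sprintf("locus_%02d.faa", i))
                writeMultiFasta(loci[[i]]@records, subFa)
                runAnalysis("call-locus", input = subFa,
                            libraryPath = libraryPath,
                            registryPath = registryPath, outputDir = sub,
                            k = k, alpha = alpha, majority = majority,
                            threshold = threshold, layout = layout,
                            shellOnlyVotes = shellOnlyVotes)
            }
        }
        inputPaths <- c(input, libraryPath)
    } else if (mode == "build-profiles") {
        if (is.null(input) || length(input) == 0L)
            stopInput("build-profiles needs at least one aligned FASTA file")
        profs <- lapply(input, function(p) {
            if (!file.exists(p)) stopInput("MSA file not found: '%s'", p)
            msa <- as.character(Biostrings::readAAStringSet(p))
            buildProfile(msa, name = sub("\\.[^.]*$", "", basename(p)),
                         threshold = threshold %||% 20)
        })
        types <- vapply(profs, profileType, "")
        lib <- profileLibrary(profs,
            mode = if (all(types != "generic")) "type_specific" else "generic")
        result$library <- lib
        libOut <- file.path(outputDir, "profiles.library")
        writeProfileLibrary(lib, libOut)
        outputs <- c(outputs, libOut)
        inputPaths <- input
    } else if (mode == "db") {
        reg <- loadReg()
        tab <- listTypes(reg, filter = if (is.null(input)) NULL else input)
        result$types <- tab
        outputs <- c(outputs, .writeTSV(tab, file.path(outputDir,
                                                       "types.tsv")))
        inputPaths <- registryPath %||% defaultRegistryPath()
    } else if (mode == "simulate") {
        world <- do.call(generateWorld, c(list(seed = seed), worldParams))
        result$world <- world
        writeWorld(world, outputDir)
        outputs <- c(outputs, file.path(outputDir, "truth.tsv"))
        inputPaths <- character(0)
    }
    result$manifest <- .manifest(outputDir, mode, params,
                                 inputPaths, basename(outputs))
    log("done: %d artifacts in %s", length(outputs), outputDir)
    invisible(result)
}
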