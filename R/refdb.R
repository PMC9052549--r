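# The packaged BMC type registry: load/save, listing, export, summaries.

#' Load a BMC type registry file
#'
#' The registry is a line-oriented structured text file. Each entry starts
#' with `TYPE <id>`, followed by `DESC <text>`, optional `INV <comma-
#' separated profile names>`, one or more `FP <locus_id>|<comma-separated
#' labels>` example fingerprints, optional `SEQ <id> <sequence>` rows, and
#' `END`. Duplicate type ids and entries without a fingerprint are
#' rejected.
#'
#' @param path Registry file path; defaults to the registry shipped with
#'   the package, which enumerates the 68 BMC types/subtypes of the
#'   published classification scheme.
#' @return A [TypeRegistry-class].
#' @export
loadRegistry <- function(path = defaultRegistryPath()) {
    if (!file.exists(path)) stopInput("registry file not found: '%s'", path)
    lines <- readLines(path)
    entries <- list()
    cur <- NULL
    for (ln in seq_along(lines)) {
        raw <- trimws(lines[ln])
        if (!nzchar(raw) || startsWith(raw, "#")) next
        sp <- regexpr("\\s", raw)
        key <- if (sp > 0) substr(raw, 1, sp - 1) else raw
        rest <- if (sp > 0) trimws(substr(raw, sp + 1, nchar(raw))) else ""
        if (key == "TYPE") {
            if (!is.null(cur))
                stopInput("line %d: TYPE before END of '%s'", ln, cur$type_id)
            if (!nzchar(rest)) stopInput("line %d: TYPE without id", ln)
            if (rest %in% names(entries))
                stopInput("line %d: duplicate type id '%s'", ln, rest)
            cur <- list(type_id = rest, description = "",
                        fingerprints = list(), inventory = character(0),
                        sequences = character(0))
        } else if (is.null(cur)) {
            stopInput("line %d: '%s' outside a TYPE entry", ln, key)
        } else if (key == "DESC") {
            cur$description <- rest
        } else if (key == "INV") {
            cur$inventory <- strsplit(rest, ",", fixed = TRUE)[[1]]
        } else if (key == "FP") {
            parts <- strsplit(rest, "|", fixed = TRUE)[[1]]
            if (length(parts) != 2L)
                stopInput("line %d: FP must be '<locus_id>|<labels>'", ln)
            cur$fingerprints <- c(cur$fingerprints,
                fingerprint(strsplit(parts[2], ",", fixed = TRUE)[[1]],
                            locusId = parts[1]))
        } else if (key == "SEQ") {
            t <- strsplit(rest, "\\s+")[[1]]
            if (length(t) != 2L) stopInput("line %d: SEQ must be '<id> <seq>'", ln)
            cur$sequences[t[1]] <- t[2]
        } else if (key == "END") {
            if (length(cur$fingerprints) == 0L)
                stopInput("line %d: type '%s' has no example fingerprint",
                          ln, cur$type_id)
            entries[[cur$type_id]] <- cur
            cur <- NULL
        } else {
            stopInput("line %d: unknown key '%s'", ln, key)
        }
    }
    if (!is.null(cur))
        stopInput("registry truncated: type '%s' missing END", cur$type_id)
    if (length(entries) == 0L) stopInput("registry '%s' has no entries", path)
    new("TypeRegistry", entries = entries)
}

#' @rdname loadRegistry
#' @export
defaultRegistryPath <- function() {
    system.file("extdata", "bmc_types.registry", package = "bmctyper",
                mustWork = TRUE)
}

#' Save a type registry to its text format
#'
#' `loadRegistry(saveRegistry(x, path))` is the identity.
#'
#' @param registry A [TypeRegistry-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
saveRegistry <- function(registry, path) {
    stopifnot(is(registry, "TypeRegistry"))
    out <- "# bmctyper type registry v1"
    for (e in registry@entries) {
        out <- c(out, paste("TYPE", e$type_id))
        if (nzchar(e$description)) out <- c(out, paste("DESC", e$description))
        if (length(e$inventory))
            out <- c(out, paste("INV", paste(e$inventory, collapse = ",")))
        for (fp in e$fingerprints)
            out <- c(out, paste0("FP ", locusId(fp), "|",
                                 paste(fingerprintLabels(fp), collapse = ",")))
        if (length(e$sequences))
            out <- c(out, paste("SEQ", names(e$sequences), e$sequences))
        out <- c(out, "END")
    }
    writeLines(out, path)
    invisible(path)
}

#' List registry types
#'
#' @param registry A [TypeRegistry-class].
#' @param filter Optional case-insensitive substring filter on the type id.
#' @return A `data.frame` (lexicographic type order) with columns
#'   `type_id`, `description`, `n_fingerprints`, `n_sequences`.
#' @export
listTypes <- function(registry, filter = NULL) {
    stopifnot(is(registry, "TypeRegistry"))
    e <- registry@entries[order(names(registry@entries))]
    tab <- data.frame(
        type_id = vapply(e, `[[`, "", "type_id"),
        description = vapply(e, `[[`, "", "description"),
        n_fingerprints = vapply(e, function(x) length(x$fingerprints), 0L),
        n_sequences = vapply(e, function(x) length(x$sequences), 0L),
        stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    if (!is.null(filter) && nzchar(filter))
        tab <- tab[grepl(tolower(filter), tolower(tab$type_id), fixed = TRUE), ,
                   drop = FALSE]
    rownames(tab) <- NULL
    tab
}

#' Export the sequences and fingerprint of a registry type
#'
#' Writes the sequences attached to a type as multi-FASTA (round-trips
#' through [readMultiFasta()]) and its example fingerprints as a small
#' fingerprint text file.
#'
#' @param registry A [TypeRegistry-class].
#' @param typeId Registry type id.
#' @param fastaPath Output FASTA path.
#' @param fingerprintPath Optional output path for the fingerprint lines.
#' @return Invisibly, the record data frame written.
#' @export
exportType <- function(registry, typeId, fastaPath,
                       fingerprintPath = NULL) {
    stopifnot(is(registry, "TypeRegistry"))
    e <- registry@entries[[typeId]]
    if (is.null(e)) stopInput("unknown type id '%s'", typeId)
    if (length(e$sequences) == 0L)
        stopInput("type '%s' has no sequences attached", typeId)
    recs <- data.frame(id = names(e$sequences), description = "",
                       index = seq_along(e$sequences) - 1L,
                       seq = unname(e$sequences), stringsAsFactors = FALSE)
    writeMultiFasta(recs, fastaPath)
    if (!is.null(fingerprintPath)) {
        writeLines(vapply(e$fingerprints, function(fp)
            paste0(locusId(fp), "\t",
                   paste(fingerprintLabels(fp), collapse = ",")), ""),
            fingerprintPath)
    }
    invisible(recs)
}

#' Summary statistics for the sequences of a registry type
#'
#' Reduces the per-profile sequence metadata of the original web resource
#' to sequence count, length min/mean/max, and isoelectric point
#' min/mean/max (computed by the standard Henderson-Hasselbalch pKa
#' bisection method via `seqinr::computePI`).
#'
#' @param registry A [TypeRegistry-class].
#' @param typeId Registry type id (must have sequences attached).
#' @return A one-row `data.frame` with the statistics.
#' @export
typeStats <- function(registry, typeId) {
    e <- registry@entries[[typeId]]
    if (is.null(e)) stopInput("unknown type id '%s'", typeId)
    if (length(e$sequences) == 0L)
        stopInput("type '%s' has no sequences attached", typeId)
    lens <- nchar(e$sequences)
    pis <- vapply(e$sequences,
                  function(s) seqinr::computePI(seqinr::s2c(s)), 0)
    data.frame(type_id = typeId, n = length(lens),
               len_min = min(lens), len_mean = mean(lens), len_max = max(lens),
               pi_min = min(pis), pi_mean = mean(pis), pi_max = max(pis),
               stringsAsFactors = FALSE)
}
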