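# HMMER3/f ASCII import and the native library serialization format.

#' Import a HMMER3 ASCII profile file
#'
#' Reads one or more records in HMMER3/f ASCII format (`HMMER3/f` header,
#' `HMM`/`COMPO`/match-state lines, terminating `//`) into a
#' [ProfileLibrary-class]. Stored negative-log probabilities are converted
#' back to probabilities; because the container uses a single shared insert
#' emission vector and strictly positive probabilities, per-state insert
#' rows are averaged and zero probabilities (`*` entries) are floored at
#' 1e-8 before renormalizing. Role and BMC type are parsed from the profile
#' name when it follows the naming convention (see [classifyRole()]).
#'
#' @param input Path to a HMMER3 ASCII file, or its lines as a character
#'   vector.
#' @param mode Library mode for the result (default `"generic"`).
#' @param threshold Acceptance threshold attached to each profile.
#' @return A [ProfileLibrary-class].
#' @export
importHMMER3 <- function(input, mode = "generic", threshold = 20) {
    lines <- if (length(input) == 1L && !grepl("\n", input) && file.exists(input))
        readLines(input) else unlist(strsplit(input, "\n", fixed = TRUE))
    n <- length(lines)
    i <- 1L
    skipBlank <- function(i) {
        while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
        i
    }
    toks <- function(i) strsplit(trimws(lines[i]), "\\s+")[[1]]
    num <- function(x, i) {
        v <- suppressWarnings(ifelse(x == "*", Inf, as.numeric(x)))
        if (anyNA(v)) stopInput("line %d: non-numeric value '%s'",
                                i, x[which(is.na(v))[1]])
        v
    }
    profs <- list()
    repeat {
        i <- skipBlank(i)
        if (i > n) break
        if (!grepl("^HMMER3/f", lines[i]))
            stopInput("line %d: expected 'HMMER3/f' header, got '%s'",
                      i, trimws(lines[i]))
        i <- i + 1L
        name <- NULL; leng <- NULL; alphOrder <- NULL
        while (i <= n && !grepl("^HMM\\s", lines[i])) {
            t <- toks(i)
            if (length(t) >= 2L) {
                if (t[1] == "NAME") name <- t[2]
                if (t[1] == "LENG") leng <- as.integer(t[2])
            }
            i <- i + 1L
        }
        if (i > n) stopInput("line %d: truncated record, no HMM line", n)
        if (is.null(name) || is.null(leng) || is.na(leng))
            stopInput("line %d: record missing NAME or LENG", i)
        alphOrder <- toks(i)[-1]
        if (length(alphOrder) != 20L || !setequal(alphOrder, AA20))
            stopInput("line %d: HMM line must list the 20 amino acids", i)
        i <- i + 1L  # transition label line
        if (i > n) stopInput("line %d: truncated record", n)
        i <- i + 1L
        i <- skipBlank(i)
        if (i <= n && identical(toks(i)[1], "COMPO")) i <- i + 1L
        # node 0: insert emissions + transitions (parsed, not stored)
        i <- i + 2L
        matEm <- matrix(0, 20, leng, dimnames = list(AA20, NULL))
        insRows <- matrix(0, 20, leng, dimnames = list(AA20, NULL))
        trans <- matrix(0, 7, max(leng - 1L, 0L),
                        dimnames = list(c("mm", "mi", "md", "im", "ii",
                                          "dm", "dd"), NULL))
        for (k in seq_len(leng)) {
            i <- skipBlank(i)
            if (i + 2L > n) stopInput("line %d: truncated record at node %d", n, k)
            t <- toks(i)
            if (!identical(suppressWarnings(as.integer(t[1])), k))
                stopInput("line %d: expected match state %d, got '%s'", i, k, t[1])
            if (length(t) < 21L) stopInput("line %d: too few match emissions", i)
            matEm[alphOrder, k] <- exp(-num(t[2:21], i))
            i <- i + 1L
            t <- toks(i)
            if (length(t) < 20L) stopInput("line %d: too few insert emissions", i)
            insRows[alphOrder, k] <- exp(-num(t[1:20], i))
            i <- i + 1L
            t <- toks(i)
            if (length(t) < 7L) stopInput("line %d: too few transitions", i)
            if (k < leng) trans[, k] <- exp(-num(t[1:7], i))
            i <- i + 1L
        }
        i <- skipBlank(i)
        if (i > n || trimws(lines[i]) != "//")
            stopInput("line %d: record for '%s' missing terminating '//'",
                      min(i, n), name)
        i <- i + 1L

        floorNorm <- function(x) { x <- pmax(x, 1e-8); x / sum(x) }
        matEm <- apply(matEm, 2L, floorNorm)
        matEm <- matrix(matEm, 20, leng, dimnames = list(AA20, NULL))
        insEm <- setNames(floorNorm(rowMeans(insRows)), AA20)
        if (leng > 1L) {
            trans[1:3, ] <- apply(trans[1:3, , drop = FALSE], 2L, floorNorm)
            trans[4:5, ] <- apply(trans[4:5, , drop = FALSE], 2L, floorNorm)
            trans[6:7, ] <- apply(trans[6:7, , drop = FALSE], 2L, floorNorm)
        }
        parsed <- classifyRole(name)
        profs[[name]] <- new("ProfileHMM", name = name, role = parsed$role,
            bmcType = if (is.na(parsed$bmcType)) "generic" else parsed$bmcType,
            matchEmissions = matEm, insertEmissions = insEm,
            transitions = trans, background = uniformBackground(),
            nTrain = 0L, threshold = threshold)
    }
    if (length(profs) == 0L) stopInput("no HMMER3 records found")
    profileLibrary(profs, mode = mode)
}

#' Write and read the native profile library text format
#'
#' A single structured text file serializing every profile of a library at
#' full double precision, so that `readProfileLibrary(writeProfileLibrary(x))`
#' round-trips exactly. The format is line-oriented: a `# bmctyper profile
#' library v1` header, a `MODE` line, then per profile `PROFILE`, `ROLE`,
#' `TYPE`, `LENG`, `NTRAIN`, `THRESH`, `BG`, `INSEM`, per-state `MATCH` and
#' `TRANS` lines, and `END`.
#'
#' @param library A [ProfileLibrary-class].
#' @param path Output (input) file path.
#' @return `writeProfileLibrary` returns `path` invisibly;
#'   `readProfileLibrary` returns a [ProfileLibrary-class].
#' @export
writeProfileLibrary <- function(library, path) {
    stopifnot(is(library, "ProfileLibrary"))
    out <- c("# bmctyper profile library v1",
             paste("MODE", library@mode))
    for (p in library@profiles) {
        L <- ncol(p@matchEmissions)
        out <- c(out,
                 paste("PROFILE", p@name),
                 paste("ROLE", p@role),
                 paste("TYPE", p@bmcType),
                 paste("LENG", L),
                 paste("NTRAIN", p@nTrain),
                 paste("THRESH", fmtNum(p@threshold)),
                 paste(c("BG", fmtNum(p@background)), collapse = " "),
                 paste(c("INSEM", fmtNum(p@insertEmissions)), collapse = " "),
                 vapply(seq_len(L), function(k)
                     paste(c("MATCH", k, fmtNum(p@matchEmissions[, k])),
                           collapse = " "), ""),
                 if (L > 1L) vapply(seq_len(L - 1L), function(k)
                     paste(c("TRANS", k, fmtNum(p@transitions[, k])),
                           collapse = " "), ""),
                 "END")
    }
    writeLines(out, path)
    invisible(path)
}

#' @rdname writeProfileLibrary
#' @export
readProfileLibrary <- function(path) {
    lines <- readLines(path)
    if (length(lines) == 0L || !grepl("^# bmctyper profile library", lines[1]))
        stopInput("'%s' is not a bmctyper profile library file", path)
    mode <- "generic"
    profs <- list()
    cur <- NULL
    finish <- function(cur) {
        new("ProfileHMM", name = cur$name, role = cur$role,
            bmcType = cur$type,
            matchEmissions = matrix(unlist(cur$match), 20, cur$leng,
                                    dimnames = list(AA20, NULL)),
            insertEmissions = setNames(cur$insem, AA20),
            transitions = matrix(unlist(cur$trans), 7,
                                 max(cur$leng - 1L, 0L),
                                 dimnames = list(c("mm", "mi", "md", "im",
                                                   "ii", "dm", "dd"), NULL)),
            background = setNames(cur$bg, AA20),
            nTrain = cur$ntrain, threshold = cur$thresh)
    }
    for (ln in seq_along(lines)[-1]) {
        t <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
        if (length(t) == 0L || !nzchar(t[1])) next
        key <- t[1]
        if (key == "MODE") mode <- t[2]
        else if (key == "PROFILE") cur <- list(name = t[2], match = list(),
                                               trans = list())
        else if (is.null(cur)) stopInput("line %d: content before PROFILE", ln)
        else if (key == "ROLE") cur$role <- t[2]
        else if (key == "TYPE") cur$type <- t[2]
        else if (key == "LENG") cur$leng <- as.integer(t[2])
        else if (key == "NTRAIN") cur$ntrain <- as.integer(t[2])
        else if (key == "THRESH") cur$thresh <- as.numeric(t[2])
        else if (key == "BG") cur$bg <- as.numeric(t[-1])
        else if (key == "INSEM") cur$insem <- as.numeric(t[-1])
        else if (key == "MATCH") cur$match[[as.integer(t[2])]] <- as.numeric(t[-(1:2)])
        else if (key == "TRANS") cur$trans[[as.integer(t[2])]] <- as.numeric(t[-(1:2)])
        else if (key == "END") { p <- finish(cur); profs[[p@name]] <- p; cur <- NULL }
        else stopInput("line %d: unknown key '%s'", ln, key)
    }
    if (length(profs) == 0L) stopInput("no profiles in '%s'", path)
    profileLibrary(profs, mode = mode)
}
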