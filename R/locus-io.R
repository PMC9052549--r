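# Ordered multi-FASTA input and candidate-locus delimitation.

#' Read an ordered protein multi-FASTA file
#'
#' Reads protein records in file order, which the downstream analysis
#' trusts as genome (gene) order. Sequences are upper-cased, trailing `*`
#' stop symbols are stripped (end only), and CRLF line endings are
#' tolerated. Duplicate identifiers, empty sequences, and inputs without
#' any record are rejected with a diagnostic naming the record.
#'
#' @param path Path to a multi-FASTA file.
#' @param text Alternatively, the FASTA content as a single string or
#'   character vector of lines.
#' @return A `data.frame` with columns `id` (first whitespace-delimited
#'   header token), `description` (remainder of header), `index` (0-based
#'   input order) and `seq`.
#' @export
readMultiFasta <- function(path = NULL, text = NULL) {
    if (is.null(path) == is.null(text))
        stopInput("provide exactly one of 'path' or 'text'")
    if (!is.null(path)) {
        if (!file.exists(path)) stopInput("file not found: '%s'", path)
        text <- readLines(path, warn = FALSE)
    } else if (length(text) == 1L) {
        text <- strsplit(text, "\n", fixed = TRUE)[[1]]
    }
    text <- sub("\r$", "", text)
    if (!any(grepl("^>", text)))
        stopInput("no FASTA records found (no '>' header)")
    tmp <- tempfile(fileext = ".faa")
    on.exit(unlink(tmp))
    writeLines(text, tmp)
    x <- Biostrings::readAAStringSet(tmp)
    if (length(x) == 0L) stopInput("no FASTA records found")
    headers <- names(x)
    ids <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers),
                   sub("^\\S+\\s+", "", headers), "")
    if (anyDuplicated(ids))
        stopInput("duplicate record id '%s'", ids[duplicated(ids)][1])
    seqs <- toupper(as.character(x))
    seqs <- sub("\\*+$", "", seqs)
    if (any(nchar(seqs) == 0L))
        stopInput("record '%s' has an empty sequence",
                  ids[which(nchar(seqs) == 0L)[1]])
    data.frame(id = unname(ids), description = unname(desc),
               index = seq_along(ids) - 1L, seq = unname(seqs),
               stringsAsFactors = FALSE)
}

#' Write protein records as multi-FASTA
#'
#' Inverse of [readMultiFasta()]: identity on `(id, seq)` pairs.
#'
#' @param records Protein record data frame (columns `id`, `seq`, optional
#'   `description`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMultiFasta <- function(records, path) {
    records <- .asRecords(records)
    hdr <- records$id
    if (!is.null(records$description)) {
        hdr <- ifelse(nzchar(records$description),
                      paste(records$id, records$description), records$id)
    }
    x <- Biostrings::AAStringSet(setNames(records$seq, hdr))
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Delimit candidate BMC loci around shell-protein hits
#'
#' Expands each shell-protein hit to a window of `window` genes on each
#' side (the locus-extraction convention of the underlying database build),
#' clips to the proteome, and merges overlapping or touching windows so
#' that a single operonic run is never split. Indices are 0-based
#' internally and in this API; reports use 1-based coordinates.
#'
#' @param records Ordered protein records ([readMultiFasta()]).
#' @param shellHitIndices 0-based indices of shell-protein hits.
#' @param window Genes on each side (default 12).
#' @return A list of [CandidateLocus-class], sorted by start; empty list
#'   when there are no hits.
#' @examples
#' recs <- data.frame(id = sprintf("g%02d", 1:60), description = "",
#'                    index = 0:59, seq = strrep("MA", 20))
#' length(extractNeighborhoods(recs, c(10, 30), window = 12))  # merged: 1
#' @export
extractNeighborhoods <- function(records, shellHitIndices, window = 12L) {
    records <- .asRecords(records)
    n <- nrow(records)
    if (length(shellHitIndices) == 0L) return(list())
    idx <- as.integer(shellHitIndices)
    if (any(is.na(idx)) || any(idx < 0L) || any(idx >= n))
        stopInput("shell hit indices must be 0-based and within the proteome")
    window <- as.integer(window)
    if (is.na(window) || window < 0L) stopInput("window must be >= 0")
    # 1-based IRanges; reduce() merges overlapping and adjacent windows
    r <- IRanges::IRanges(start = pmax(idx - window, 0L) + 1L,
                          end = pmin(idx + window, n - 1L) + 1L)
    merged <- IRanges::reduce(r, min.gapwidth = 1L)
    lapply(seq_along(merged), function(i) {
        s <- IRanges::start(merged)[i] - 1L
        e <- IRanges::end(merged)[i] - 1L
        new("CandidateLocus",
            records = records[records$index >= s & records$index <= e, ,
                              drop = FALSE],
            anchorIndices = sort(idx[idx >= s & idx <= e]),
            window = window, start = s, end = e)
    })
}
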