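# Amino-acid alphabet and shared small utilities.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity / non-standard letters tolerated in input; scored with the
# background distribution (log-odds 0) and skipped when training profiles.
AA_NONSTANDARD <- c("B", "J", "O", "U", "X", "Z")

GAP_CHARS <- c("-", ".")

#' Uniform amino-acid background distribution
#'
#' The default null model: each of the 20 standard residues with
#' probability 1/20. Libraries may carry their own background.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
uniformBackground <- function() {
    setNames(rep(1 / 20, 20), AA20)
}

# Map a protein string to 0-based residue indices; -1 for non-standard
# letters (treated as background by the scorer). Errors on anything else.
aaIndex <- function(seq) {
    chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
    idx <- match(chars, AA20) - 1L
    bad <- is.na(idx) & !(chars %in% AA_NONSTANDARD)
    if (any(bad)) {
        stopInput(sprintf("invalid residue '%s' at position %d",
                          chars[which(bad)[1]], which(bad)[1]))
    }
    idx[is.na(idx)] <- -1L
    idx
}

randomAAString <- function(n) {
    paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# Condition constructors used across modules; the CLI maps the classes to
# exit codes (input error -> 2, empty/degenerate analysis -> 3).
stopInput <- function(...) {
    stop(structure(class = c("bmc_input_error", "error", "condition"),
                   list(message = sprintf(...), call = sys.call(-1))))
}

stopEmpty <- function(...) {
    stop(structure(class = c("bmc_empty_error", "error", "condition"),
                   list(message = sprintf(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmtNum <- function(x) sprintf("%.17g", x)
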