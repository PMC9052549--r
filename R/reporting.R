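# SVG locus diagrams, HTML report, and external-link helpers.

# Geometry constants for the locus diagram.
PX_PER_RESIDUE <- 0.6
BAR_HEIGHT <- 16
ROW_HEIGHT <- 56
BAR_GAP <- 8
MARGIN <- 12

.svgEscape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
}

.labelColor <- function(bmcType, modalType) {
    if (is.na(bmcType)) return("grey")
    if (!is.na(modalType) && bmcType == modalType) return("green") else return("red")
}

#' Render a locus diagram as SVG
#'
#' Draws one bar per protein in locus order. Bar length is strictly
#' proportional to residue count; bar fill follows the fixed role color
#' scheme ([roleColors()]). The identifier/profile label under each bar is
#' green when the assignment's BMC type equals the called modal type, red
#' when it is typed otherwise, and grey when untyped. The `cascading`
#' layout wraps rows after `rowWidth` genes (suited to typical 20-30 gene
#' BMC loci); `linear` draws a single row.
#'
#' @param records Protein records of the locus ([readMultiFasta()] order).
#' @param assignments Best-assignment rows aligned 1:1 with `records`.
#' @param typeCall A [TypeAssignment-class] for the locus (used for label
#'   coloring); may be `NULL`.
#' @param layout `"cascading"` (default) or `"linear"`.
#' @param rowWidth Genes per row in the cascading layout (default 10).
#' @return A single string containing a standalone SVG 1.1 document.
#' @export
renderLocus <- function(records, assignments, typeCall = NULL,
                        layout = c("cascading", "linear"), rowWidth = 10L) {
    layout <- match.arg(layout)
    records <- .asRecords(records)
    if (nrow(records) != nrow(assignments))
        stopInput("assignments (%d) do not align with locus records (%d)",
                  nrow(assignments), nrow(records))
    modal <- if (!is.null(typeCall)) assignedType(typeCall) else NA_character_
    n <- nrow(records)
    rows <- if (layout == "cascading") split(seq_len(n),
                (seq_len(n) - 1L) %/% rowWidth) else list(seq_len(n))
    body <- character(0)
    maxX <- 0
    for (r in seq_along(rows)) {
        x <- MARGIN
        y <- MARGIN + (r - 1L) * ROW_HEIGHT
        for (i in rows[[r]]) {
            w <- nchar(records$seq[i]) * PX_PER_RESIDUE
            role <- assignments$role[i]
            fill <- unname(ROLE_COLORS[role])
            lab <- if (!is.na(assignments$profile_name[i]))
                paste0(records$id[i], " (", assignments$profile_name[i], ")")
            else records$id[i]
            lcol <- .labelColor(assignments$bmc_type[i], modal)
            body <- c(body,
                sprintf('<rect x="%.2f" y="%.2f" width="%.2f" height="%d" fill="%s" stroke="black" stroke-width="0.5"><title>%s</title></rect>',
                        x, y, w, BAR_HEIGHT, fill, .svgEscape(records$id[i])),
                sprintf('<text x="%.2f" y="%.2f" font-size="9" font-family="sans-serif" fill="%s">%s</text>',
                        x, y + BAR_HEIGHT + 11, lcol, .svgEscape(lab)))
            x <- x + w + BAR_GAP
        }
        maxX <- max(maxX, x)
    }
    height <- MARGIN * 2 + length(rows) * ROW_HEIGHT
    paste0(sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%.0f" height="%d">',
                   maxX + MARGIN + 240, height),
           paste(body, collapse = ""), "</svg>")
}

#' Render a self-contained HTML locus report
#'
#' Wraps the SVG diagram with the analysis tables: the type call with its
#' vote table (and signature-enzyme hint when ambiguous), the per-protein
#' best assignments, and the closest-types ranking. Static HTML, no server
#' required.
#'
#' @inheritParams renderLocus
#' @param closest Optional closest-types data frame ([rankClosest()]).
#' @param title Page title.
#' @return A single HTML string.
#' @export
renderLocusHTML <- function(records, assignments, typeCall = NULL,
                            closest = NULL, layout = "cascading",
                            rowWidth = 10L, title = "BMC locus analysis") {
    svg <- renderLocus(records, assignments, typeCall, layout, rowWidth)
    tabHTML <- function(df) {
        hdr <- paste0("<tr>", paste0("<th>", .svgEscape(names(df)), "</th>",
                                     collapse = ""), "</tr>")
        rows <- apply(df, 1L, function(r)
            paste0("<tr>", paste0("<td>", .svgEscape(as.character(r)), "</td>",
                                  collapse = ""), "</tr>"))
        paste0("<table border='1' cellspacing='0' cellpadding='3'>", hdr,
               paste(rows, collapse = ""), "</table>")
    }
    call_html <- ""
    if (!is.null(typeCall)) {
        votes <- voteTable(typeCall)
        call_html <- paste0(
            "<h2>BMC type assignment</h2><p>Type: <b>",
            .svgEscape(ifelse(is.na(assignedType(typeCall)), "none",
                              assignedType(typeCall))),
            "</b> | status: ", typingStatus(typeCall),
            sprintf(" | confidence: %.3f</p>", confidence(typeCall)),
            if (length(votes)) paste0("<p>Votes: ",
                paste(sprintf("%s=%d", names(votes), votes), collapse = ", "),
                "</p>") else "",
            if (typingStatus(typeCall) == "ambiguous" &&
                length(signatureTypes(typeCall)))
                paste0("<p>Signature enzyme types: ",
                       paste(signatureTypes(typeCall), collapse = ", "),
                       "</p>") else "")
    }
    paste0("<!DOCTYPE html><html><head><meta charset='utf-8'><title>",
           .svgEscape(title), "</title></head><body><h1>",
           .svgEscape(title), "</h1>", call_html,
           "<h2>Locus diagram</h2>", svg,
           "<h2>Best profile matches</h2>", tabHTML(assignments),
           if (!is.null(closest)) paste0("<h2>Closest BMC types</h2>",
                                         tabHTML(closest)) else "",
           "</body></html>")
}

#' SWISS-MODEL homology-modelling link for a sequence
#'
#' Deterministic URL embedding the sequence in the SWISS-MODEL interactive
#' submission interface; no network call is made.
#'
#' @param seq Protein sequence (non-empty).
#' @return URL string containing the exact sequence.
#' @export
swissModelLink <- function(seq) {
    if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
        stopInput("empty sequence")
    paste0("https://swissmodel.expasy.org/interactive?seq=", seq)
}
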