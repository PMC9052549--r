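mkAsg <- function(ids, names, bits = 30) {
    do.call(rbind, lapply(seq_along(ids), function(i) {
        nm <- names[i]
        if (is.na(nm)) {
            data.frame(query_id = ids[i], profile_name = NA_character_,
                       role = "NONE", bmc_type = NA_character_,
                       bitscore = NA_real_, is_shell = FALSE,
                       n_domains = NA_integer_, stringsAsFactors = FALSE)
        } else {
            parsed <- classifyRole(nm)
            data.frame(query_id = ids[i], profile_name = nm,
                       role = parsed$role, bmc_type = parsed$bmcType,
                       bitscore = bits, is_shell = parsed$role %in% shellRoles(),
                       n_domains = 1L, stringsAsFactors = FALSE)
        }
    }))
}

demoLocus <- function() {
    recs <- data.frame(id = c("g1", "g2", "g3"), description = "",
                       index = 0:2,
                       seq = c(strrep("M", 100), strrep("A", 200),
                               strrep("K", 150)),
                       stringsAsFactors = FALSE)
    asg <- mkAsg(recs$id, c("SPU1__P_amber", "SPU1__H_azure",
                            "ACI__H_coral"))
    tc <- callType(asg)
    list(recs = recs, asg = asg, tc = tc)
}

test_that("locus diagrams are well-formed SVG with proportional bars", {
    d <- demoLocus()
    svg <- renderLocus(d$recs, d$asg, d$tc)
    doc <- xml2::read_xml(svg)
    rects <- xml2::xml_find_all(doc, ".//*[local-name()='rect']")
    expect_length(rects, 3L)
    widths <- as.numeric(xml2::xml_attr(rects, "width"))
    expect_equal(widths[2] / widths[1], 2, tolerance = 1e-9)
    expect_equal(widths[3] / widths[1], 1.5, tolerance = 1e-9)
    # BMC-P bar is yellow, BMC-H bars blue
    fills <- xml2::xml_attr(rects, "fill")
    expect_equal(fills, c("yellow", "blue", "blue"))
})

test_that("label colors encode agreement with the modal type", {
    d <- demoLocus()
    expect_equal(assignedType(d$tc), "SPU1")
    svg <- renderLocus(d$recs, d$asg, d$tc)
    doc <- xml2::read_xml(svg)
    texts <- xml2::xml_find_all(doc, ".//*[local-name()='text']")
    cols <- xml2::xml_attr(texts, "fill")
    expect_equal(cols, c("green", "green", "red"))
    # untyped proteins get grey labels
    asg2 <- d$asg; asg2[3, ] <- mkAsg("g3", NA)[1, ]
    svg2 <- renderLocus(d$recs, asg2, callType(asg2))
    cols2 <- xml2::xml_attr(xml2::xml_find_all(xml2::read_xml(svg2),
                                               ".//*[local-name()='text']"),
                            "fill")
    expect_equal(cols2[3], "grey")
})

test_that("layouts wrap rows and rendering is deterministic", {
    n <- 25
    recs <- data.frame(id = sprintf("g%02d", 1:n), description = "",
                       index = 0:(n - 1), seq = strrep("M", 80),
                       stringsAsFactors = FALSE)
    asg <- mkAsg(recs$id, rep(c("SPU1__H_a", NA), length.out = n))
    tc <- callType(asg)
    casc <- renderLocus(recs, asg, tc, layout = "cascading", rowWidth = 10)
    linear <- renderLocus(recs, asg, tc, layout = "linear")
    ys <- function(svg) unique(xml2::xml_attr(xml2::xml_find_all(
        xml2::read_xml(svg), ".//*[local-name()='rect']"), "y"))
    expect_length(ys(casc), 3L)   # 25 genes at 10 per row
    expect_length(ys(linear), 1L)
    expect_identical(casc, renderLocus(recs, asg, tc, layout = "cascading",
                                       rowWidth = 10))
    expect_error(renderLocus(recs, asg[1:3, ], tc), "align",
                 class = "bmc_input_error")
})

test_that("the HTML report is self-contained and embeds the pieces", {
    d <- demoLocus()
    closest <- data.frame(rank = 1L, type = "SPU1", value = 1,
                          inventory = 1, order = 1, offset = 0L,
                          orientation = "forward")
    html <- renderLocusHTML(d$recs, d$asg, d$tc, closest = closest)
    expect_match(html, "^<!DOCTYPE html>")
    expect_match(html, "<svg", fixed = TRUE)
    expect_match(html, "SPU1", fixed = TRUE)
    expect_match(html, "Closest BMC types", fixed = TRUE)
})

test_that("SWISS-MODEL links are deterministic and embed the sequence", {
    u <- swissModelLink("MKVLLA")
    expect_match(u, "MKVLLA", fixed = TRUE)
    expect_identical(u, swissModelLink("MKVLLA"))
    expect_error(swissModelLink(""), "empty", class = "bmc_input_error")
})
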