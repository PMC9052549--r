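# Generates inst/extdata/bmc_types.registry: the shipped registry of the
# 68 BMC type/subtype identifiers of the published classification scheme.
# Example fingerprints are deterministic fixture-derived placeholders
# (synthetic label sequences following the profile naming convention);
# they stand in until real loci are loaded by the user.
# Run from the repository root: Rscript data-raw/make_registry.R

suppressPackageStartupMessages(pkgload::load_all("."))

typeIds <- c(
    "ACI",
    "BUF1", "BUF2", "BUF3", "BUF4", "BUF5",
    "CCM", "CSO",
    "CUT1", "CUT2", "CUT3",
    "ETU",
    "EUT1",
    paste0("EUT2", LETTERS[1:12]),
    "EUT3",
    "GRM1A", "GRM1B", "GRM1C", "GRM2", "GRM3A", "GRM3B", "GRM3C",
    "GRM4", "GRM5",
    "HO",
    "MIC1", "MIC2", "MIC3",
    paste0("MUF", 1:10),
    paste0("PDU1", LETTERS[1:6]), "PDU2", "PDU3",
    "PVM1", "PVM2",
    "RMM1", "RMM2", "RMM3",
    paste0("SPU", 1:6))
stopifnot(length(typeIds) == 68L, !anyDuplicated(typeIds))

descFor <- function(id) {
    fam <- sub("[0-9].*$", "", id)
    base <- c(ACI = "Acidobacteria-associated metabolosome",
              BUF = "BMC of unknown function",
              CCM = "Beta-carboxysome (CO2-fixing BMC of cyanobacteria)",
              CSO = "Alpha-carboxysome (CO2-fixing BMC)",
              CUT = "Choline utilization metabolosome",
              ETU = "Ethanol utilization BMC",
              EUT = "Ethanolamine utilization metabolosome",
              GRM = "Glycyl-radical enzyme associated metabolosome",
              HO  = "Haliangium ochraceum type BMC",
              MIC = "Metabolosome with incomplete core",
              MUF = "Metabolosome of unknown function",
              PDU = "Propanediol utilization metabolosome",
              PVM = "Planctomycetes and Verrucomicrobia metabolosome",
              RMM = "Rhodococcus and Mycobacterium microcompartment",
              SPU = "Sugar phosphate utilization BMC")
    d <- base[fam]
    if (is.na(d)) d <- "Bacterial microcompartment type"
    sub <- sub("^[A-Z]+", "", id)
    if (nzchar(sub)) paste0(d, ", subtype ", sub) else unname(d)
}

# Deterministic placeholder fingerprints: one synthetic example locus per
# type, labels following <TYPE>__<ROLE>_<color>.
set.seed(20220428)
stems <- c("P", "H", "Hp", "Ts", "Tsp", "Tdp", "SIG", "REG", "ALDDH",
           "ALCDH", "PTAC")
colors <- bmctyper:::FIXTURE_COLORS

entries <- list()
for (id in typeIds) {
    nRoles <- sample(5:9, 1)
    # every example locus leads with shell components, then enzymes
    roles <- unique(c(sample(c("H", "P", "Hp", "Ts"), 2),
                      sample(stems, nRoles)))
    labels <- paste0(id, "__", roles, "_", sample(colors, length(roles)))
    # paralogs: duplicate one or two shell labels, as real loci do
    dup <- labels[grepl("__H_|__P_", labels)]
    if (length(dup)) labels <- append(labels, dup[1], after = sample(length(labels), 1))
    entries[[id]] <- list(type_id = id, description = descFor(id),
                          fingerprints = list(fingerprint(labels,
                              locusId = paste0(id, "_example1"))),
                          inventory = unique(labels),
                          sequences = character(0))
}

reg <- new("TypeRegistry", entries = entries)
saveRegistry(reg, "inst/extdata/bmc_types.registry")
cat("wrote", length(entries), "types\n")
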