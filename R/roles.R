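# Functional roles of BMC locus components, their display colors, and the
# profile naming convention.

ROLE_LEVELS <- c("BMC_P", "BMC_H", "BMC_Hp", "BMC_Ts", "BMC_Tsp", "BMC_Tdp",
                 "SIGNATURE_ENZYME", "REGULATOR", "ALDDH", "ALCDH", "PTAC",
                 "OTHER_CONSERVED", "NONE")

SHELL_ROLES <- c("BMC_P", "BMC_H", "BMC_Hp", "BMC_Ts", "BMC_Tsp", "BMC_Tdp")

# Role stem used in profile names -> role.
ROLE_STEMS <- c(P = "BMC_P", H = "BMC_H", Hp = "BMC_Hp",
                Ts = "BMC_Ts", Tsp = "BMC_Tsp", Tdp = "BMC_Tdp",
                SIG = "SIGNATURE_ENZYME", REG = "REGULATOR",
                ALDDH = "ALDDH", ALCDH = "ALCDH", PTAC = "PTAC")

ROLE_COLORS <- c(BMC_P = "yellow",
                 BMC_H = "blue", BMC_Hp = "blue",
                 BMC_Ts = "lightblue", BMC_Tsp = "lightblue",
                 BMC_Tdp = "teal",
                 SIGNATURE_ENZYME = "purple",
                 REGULATOR = "orange",
                 ALDDH = "red",
                 ALCDH = "green",
                 PTAC = "magenta",
                 OTHER_CONSERVED = "black",
                 NONE = "grey")

#' Functional roles and display colors of BMC locus components
#'
#' `bmcRoles()` lists the recognized roles: the six shell protein classes
#' (BMC-P pentamers, BMC-H hexamers and the circularly permuted BMC-H^p,
#' the tandem-domain trimers BMC-T^s / BMC-T^sp / BMC-T^dp), the core
#' metabolosome enzymes (signature enzyme, aldehyde and alcohol
#' dehydrogenase, phosphotransacetylase), regulators, other conserved locus
#' proteins, and `NONE` for proteins with no accepted profile hit.
#' `roleColors()` returns the fixed diagram color for each role
#' (yellow BMC-P, blue BMC-H/BMC-H^p, light blue BMC-T^s/BMC-T^sp, teal
#' BMC-T^dp, purple signature enzyme, orange regulator, red AldDh, green
#' AlcDh, magenta PTAC, black other conserved, grey unassigned).
#' `shellRoles()` returns the six shell classes.
#'
#' @return Character vector of roles, or a named character vector of colors.
#' @export
bmcRoles <- function() ROLE_LEVELS

#' @rdname bmcRoles
#' @export
roleColors <- function() ROLE_COLORS

#' @rdname bmcRoles
#' @export
shellRoles <- function() SHELL_ROLES

#' Parse a profile name into its role and BMC type
#'
#' Profile names follow `<ROLE>_<color>` for generic profiles (e.g.
#' `H_azure`, `P_amber`) and `<TYPE>__<ROLE>_<color>` for type-specific
#' profiles (e.g. `SPU1__H_azure`), with `__` as the reserved separator.
#' Recognized role stems are `P`, `H`, `Hp`, `Ts`, `Tsp`, `Tdp` (shell),
#' `SIG`, `REG`, `ALDDH`, `ALCDH` and `PTAC`. Unknown stems and
#' non-conforming names map to `OTHER_CONSERVED`.
#'
#' @param name A profile name.
#' @return A list with elements `role` (one of [bmcRoles()]) and `bmcType`
#'   (type label, or `NA` for generic/non-conforming names).
#' @examples
#' classifyRole("SPU1__H_azure")
#' classifyRole("P_amber")
#' @export
classifyRole <- function(name) {
    stopifnot(is.character(name), length(name) == 1L)
    bmcType <- NA_character_
    rest <- name
    if (grepl("__", name, fixed = TRUE)) {
        parts <- strsplit(name, "__", fixed = TRUE)[[1]]
        if (length(parts) == 2L && nzchar(parts[1])) {
            bmcType <- parts[1]
            rest <- parts[2]
        }
    }
    toks <- strsplit(rest, "_", fixed = TRUE)[[1]]
    role <- "OTHER_CONSERVED"
    if (length(toks) >= 2L && toks[1] %in% names(ROLE_STEMS)) {
        role <- unname(ROLE_STEMS[toks[1]])
    }
    list(role = role, bmcType = bmcType)
}

roleIsShell <- function(role) role %in% SHELL_ROLES
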