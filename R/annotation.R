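# Reducing raw hits to one best assignment per protein; shell-only scans.

.emptyAssignments <- function() {
    data.frame(query_id = character(), profile_name = character(),
               role = character(), bmc_type = character(),
               bitscore = numeric(), is_shell = logical(),
               n_domains = integer(), stringsAsFactors = FALSE)
}

#' Reduce hits to the single best assignment per protein
#'
#' For every protein the hit with the maximal bitscore wins; exact ties are
#' broken by the lexicographically smallest profile name, so the result is
#' deterministic and stable under permutation of the hit list. Proteins
#' without hits receive role `NONE`.
#'
#' @param hits Named list of hit data frames as returned by
#'   [searchLibrary()], in locus/proteome order.
#' @return A `data.frame` with one row per protein, in input order:
#'   `query_id`, `profile_name` (`NA` when unassigned), `role`, `bmc_type`
#'   (`NA` when untyped), `bitscore`, `is_shell`, `n_domains`.
#' @export
assignBest <- function(hits) {
    if (length(hits) == 0L) return(.emptyAssignments())
    rows <- lapply(seq_along(hits), function(i) {
        h <- hits[[i]]
        qid <- names(hits)[i]
        if (is.null(h) || nrow(h) == 0L) {
            return(data.frame(query_id = qid, profile_name = NA_character_,
                              role = "NONE", bmc_type = NA_character_,
                              bitscore = NA_real_, is_shell = FALSE,
                              n_domains = NA_integer_,
                              stringsAsFactors = FALSE))
        }
        h <- h[order(-h$bitscore, h$profile_name), , drop = FALSE]
        best <- h[1L, ]
        parsed <- classifyRole(best$profile_name)
        data.frame(query_id = if (!is.na(best$query_id)) best$query_id else qid,
                   profile_name = best$profile_name, role = parsed$role,
                   bmc_type = parsed$bmcType, bitscore = best$bitscore,
                   is_shell = roleIsShell(parsed$role),
                   n_domains = best$n_domains, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Shell-protein-only scan of a proteome
#'
#' Uses a library restricted to shell-protein profiles to quickly identify
#' shell proteins in a whole proteome, returning only proteins with an
#' accepted shell hit (in input order) plus a count per shell class.
#'
#' @param records Ordered protein records ([readMultiFasta()]).
#' @param shellLibrary A [ProfileLibrary-class] containing only profiles
#'   whose role is one of [shellRoles()]; anything else is rejected.
#' @param threshold Optional global bitscore threshold.
#' @return A list with elements `assignments` (best-assignment rows of the
#'   shell hits) and `summary` (named integer vector over the six shell
#'   classes; sums to the number of returned assignments).
#' @export
scanShellOnly <- function(records, shellLibrary, threshold = NULL) {
    stopifnot(is(shellLibrary, "ProfileLibrary"))
    roles <- vapply(shellLibrary@profiles, profileRole, "")
    if (any(!roles %in% SHELL_ROLES))
        stopInput("shell-only scan requires a shell library; profile '%s' has role %s",
                  names(roles)[which(!roles %in% SHELL_ROLES)[1]],
                  roles[which(!roles %in% SHELL_ROLES)[1]])
    hits <- searchLibrary(shellLibrary, records, threshold = threshold)
    asg <- assignBest(hits)
    shell <- asg[asg$is_shell, , drop = FALSE]
    summary <- vapply(SHELL_ROLES, function(r) sum(shell$role == r), 0L)
    list(assignments = shell, summary = summary)
}
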