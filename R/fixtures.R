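# Seeded synthetic fixture worlds: toy protein families, training
# alignments, and labeled loci for end-to-end testing without downloads.

FIXTURE_ROLE_STEMS <- c("P", "H", "Hp", "Ts", "SIG", "ALDDH")

FIXTURE_COLORS <- c(
    "azure", "fuchsia", "amber", "coral", "teal2", "indigo", "sienna",
    "ochre", "mauve", "cerise", "umber", "jade", "lilac", "sepia", "rust",
    "olive", "plum", "mint", "navy", "peach", "ruby", "slate", "topaz",
    "ivory", "lemon", "maroon", "orchid", "pearl", "pine", "rose", "sage",
    "sand", "smoke", "snow", "steel", "straw", "tan2", "wine", "zinc",
    "aqua", "beige", "blush", "brass", "bronze", "carbon", "cedar",
    "cherry", "clay", "cloud", "cobalt", "copper", "cream", "crimson",
    "denim", "ebony", "fern", "flame", "fog", "forest", "frost", "garnet",
    "ginger", "gold", "granite", "grape", "hazel", "honey", "iris", "ivy",
    "lava", "lime2", "marble")

withWorldSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
    expr
}

.noiseMotif <- function(motif, subRate) {
    chars <- strsplit(motif, "", fixed = TRUE)[[1]]
    hit <- runif(length(chars)) < subRate
    if (any(hit)) chars[hit] <- sample(AA20, sum(hit), replace = TRUE)
    paste(chars, collapse = "")
}

#' Generate a deterministic synthetic fixture world
#'
#' Creates `nTypes` synthetic BMC types. Each type has one motif-anchored
#' protein family per role (four shell roles, a signature enzyme, and an
#' aldehyde dehydrogenase): family sequences are a conserved random motif
#' with per-position substitution noise at rate `subRate`, flanked by
#' per-sequence random spacers of fixed length (rows are equal length, so
#' each family doubles as its own training alignment). Loci place the
#' type's roles in a per-type canonical order (always starting with a
#' shell role) repeated to the core length, draw each gene from the
#' *held-out* back half of its family (so profiles trained on the front
#' half are leakage-free), insert `bystanderFrac` untyped bystander genes,
#' and apply up to `maxSwaps` adjacent swaps. Regeneration from the same
#' seed is bit-identical; all randomness flows through one seeded stream.
#'
#' @param seed Integer seed.
#' @param nTypes Number of synthetic types (>= 2).
#' @param lociPerType Loci generated per type.
#' @param locusLen Genes per locus including bystanders.
#' @param familySize Sequences per family (>= 3, the alignment-quality
#'   floor).
#' @param motifLen,spacerLen Conserved motif and flanking spacer lengths.
#' @param subRate Per-position substitution rate within the motif
#'   (default 0.1).
#' @param bystanderFrac Fraction of untyped bystander genes per locus.
#' @param maxSwaps Maximum number of adjacent order swaps per locus.
#' @return A [FixtureWorld-class].
#' @export
generateWorld <- function(seed, nTypes = 10L, lociPerType = 8L,
                          locusLen = 20L, familySize = 6L, motifLen = 48L,
                          spacerLen = 8L, subRate = 0.1,
                          bystanderFrac = 0.2, maxSwaps = 2L) {
    seed <- as.integer(seed)
    if (is.na(seed)) stopInput("seed must be an integer")
    if (nTypes < 2L) stopInput("nTypes must be >= 2")
    if (lociPerType < 1L) stopInput("lociPerType must be >= 1")
    if (locusLen < 5L) stopInput("locusLen must be >= 5")
    if (familySize < 3L) stopInput("familySize must be >= 3")
    if (motifLen < 10L) stopInput("motifLen must be >= 10")
    if (subRate < 0 || subRate >= 1) stopInput("subRate must be in [0, 1)")
    withWorldSeed(seed, {
        types <- sprintf("SYN%02d", seq_len(nTypes))
        families <- list()
        ci <- 0L
        for (ty in types) {
            for (stem in FIXTURE_ROLE_STEMS) {
                ci <- ci + 1L
                color <- if (ci <= length(FIXTURE_COLORS))
                    FIXTURE_COLORS[ci] else sprintf("hue%03d", ci)
                name <- paste0(ty, "__", stem, "_", color)
                motif <- randomAAString(motifLen)
                msa <- vapply(seq_len(familySize), function(s) {
                    paste0(randomAAString(spacerLen),
                           .noiseMotif(motif, subRate),
                           randomAAString(spacerLen))
                }, "")
                families[[name]] <- list(name = name, type = ty,
                    role = unname(ROLE_STEMS[stem]), stem = stem,
                    motif = motif, msa = msa)
            }
        }
        trainN <- ceiling(familySize / 2)
        heldOut <- (trainN + 1L):familySize
        famLookup <- new.env(parent = emptyenv())
        for (nm in names(families)) {
            f <- families[[nm]]
            famLookup[[paste(f$type, f$stem)]] <- nm
        }
        nBy <- round(bystanderFrac * locusLen)
        coreN <- locusLen - nBy
        loci <- list()
        for (ty in types) {
            canonical <- sample(FIXTURE_ROLE_STEMS)
            shellPos <- which(canonical %in% c("P", "H", "Hp", "Ts"))[1]
            canonical <- c(canonical[shellPos:length(canonical)],
                           canonical[seq_len(shellPos - 1L)])
            for (l in seq_len(lociPerType)) {
                lid <- sprintf("%s_L%02d", ty, l)
                stems <- rep(canonical, length.out = coreN)
                famNames <- vapply(stems, function(st)
                    famLookup[[paste(ty, st)]], "")
                genes <- data.frame(
                    seq = vapply(famNames, function(fn)
                        families[[fn]]$msa[sample(heldOut, 1L)], ""),
                    role_truth = unname(ROLE_STEMS[stems]),
                    family = famNames, stringsAsFactors = FALSE)
                if (nBy > 0L) {
                    by <- data.frame(
                        seq = vapply(seq_len(nBy), function(i)
                            randomAAString(motifLen + 2L * spacerLen), ""),
                        role_truth = "NONE", family = NA_character_,
                        stringsAsFactors = FALSE)
                    pos <- sort(sample(seq_len(coreN + nBy), nBy))
                    full <- data.frame(seq = character(coreN + nBy),
                                       role_truth = "", family = "",
                                       stringsAsFactors = FALSE)
                    full[pos, ] <- by
                    full[setdiff(seq_len(coreN + nBy), pos), ] <- genes
                    genes <- full
                }
                nSwaps <- sample(0:maxSwaps, 1L)
                if (nSwaps > 0L && nrow(genes) > 1L) {
                    for (sw in seq_len(nSwaps)) {
                        p <- sample(seq_len(nrow(genes) - 1L), 1L)
                        genes[c(p, p + 1L), ] <- genes[c(p + 1L, p), ]
                    }
                }
                genes <- cbind(id = sprintf("%s_g%02d", lid,
                                            seq_len(nrow(genes))),
                               genes, type_truth = ty,
                               stringsAsFactors = FALSE)
                genes$family[genes$role_truth == "NONE"] <- NA_character_
                loci[[lid]] <- genes
            }
        }
        new("FixtureWorld", seed = seed, types = types, families = families,
            loci = loci,
            params = list(nTypes = nTypes, lociPerType = lociPerType,
                          locusLen = locusLen, familySize = familySize,
                          motifLen = motifLen, spacerLen = spacerLen,
                          subRate = subRate, bystanderFrac = bystanderFrac,
                          maxSwaps = maxSwaps, trainN = trainN))
    })
}

#' Build the type-specific profile library of a fixture world
#'
#' Builds one profile per family from the first `ceiling(familySize / 2)`
#' sequences (the training half; world loci only use the held-out half).
#'
#' @param world A [FixtureWorld-class].
#' @param threshold Bitscore acceptance threshold for the profiles.
#' @return A type-specific [ProfileLibrary-class].
#' @export
worldProfileLibrary <- function(world, threshold = 20) {
    stopifnot(is(world, "FixtureWorld"))
    trainN <- world@params$trainN
    profs <- lapply(world@families, function(f)
        buildProfile(f$msa[seq_len(trainN)], name = f$name,
                     threshold = threshold))
    profileLibrary(profs, mode = "type_specific")
}

#' Build a reference registry from a fixture world's truth labels
#'
#' Uses the truth fingerprint (family names of the typed genes, in gene
#' order) of the first `nExamples` loci of each type as the registry
#' examples.
#'
#' @param world A [FixtureWorld-class].
#' @param nExamples Example loci per type (default 1).
#' @param attachSequences If `TRUE`, attach the family sequences of each
#'   type so the entry supports [exportType()]/[typeStats()].
#' @return A [TypeRegistry-class].
#' @export
worldRegistry <- function(world, nExamples = 1L, attachSequences = FALSE) {
    stopifnot(is(world, "FixtureWorld"))
    entries <- list()
    for (ty in world@types) {
        lids <- grep(paste0("^", ty, "_L"), names(world@loci), value = TRUE)
        fps <- lapply(head(lids, nExamples), function(lid) {
            truth <- worldTruthFingerprint(world, lid)
            truth
        })
        fams <- Filter(function(f) f$type == ty, world@families)
        seqs <- character(0)
        if (attachSequences) {
            for (f in fams) {
                s <- setNames(f$msa, paste0(f$name, "_s", seq_along(f$msa)))
                seqs <- c(seqs, s)
            }
        }
        entries[[ty]] <- list(type_id = ty,
            description = sprintf("synthetic fixture type %s", ty),
            fingerprints = fps,
            inventory = unname(vapply(fams, `[[`, "", "name")),
            sequences = seqs)
    }
    new("TypeRegistry", entries = entries)
}

#' Truth fingerprint of a fixture locus
#'
#' @param world A [FixtureWorld-class].
#' @param lid Locus id.
#' @return A [Fingerprint-class] built from the locus truth labels.
#' @export
worldTruthFingerprint <- function(world, lid) {
    locus <- world@loci[[lid]]
    if (is.null(locus)) stopInput("unknown locus '%s'", lid)
    fingerprint(locus$family[!is.na(locus$family)], locusId = lid)
}

#' Corrupt a fixture locus
#'
#' Deterministic corruption modes used to exercise ambiguity and novelty
#' handling: `shuffle` permutes gene order (the vote table is unchanged);
#' `mix_types` replaces just over half of the typed genes with same-role
#' genes from two other types, cycling donors so that no single type
#' retains a majority (emulating the mixed-type pattern of candidate novel
#' loci); `drop_shell` removes all shell genes.
#'
#' @param locus A fixture locus data frame (an element of [worldLoci()]).
#' @param mode One of `"shuffle"`, `"mix_types"`, `"drop_shell"`.
#' @param seed Integer seed for the corruption stream.
#' @param world The [FixtureWorld-class] the locus came from (required for
#'   `mix_types`, which draws donor genes from other types).
#' @return The corrupted locus data frame.
#' @export
corruptLocus <- function(locus, mode = c("shuffle", "mix_types",
                                         "drop_shell"),
                         seed = 1L, world = NULL) {
    mode <- match.arg(mode)
    stopifnot(is.data.frame(locus))
    withWorldSeed(as.integer(seed) + 7777L, {
        if (mode == "shuffle") {
            locus[sample(nrow(locus)), , drop = FALSE]
        } else if (mode == "drop_shell") {
            locus[!(locus$role_truth %in% SHELL_ROLES), , drop = FALSE]
        } else {
            if (is.null(world))
                stopInput("mix_types corruption needs the source world")
            ty <- locus$type_truth[1]
            donors <- setdiff(world@types, ty)
            if (length(donors) < 2L)
                stopInput("mix_types needs at least two other types")
            donors <- sample(donors, 2L)
            typedIdx <- which(!is.na(locus$family))
            t <- length(typedIdx)
            if (t < 2L) stopInput("locus has too few typed genes to mix")
            r <- floor(t / 2) + 1L
            repl <- sort(sample(typedIdx, r))
            heldOut <- (world@params$trainN + 1L):world@params$familySize
            for (j in seq_along(repl)) {
                i <- repl[j]
                donor <- donors[(j - 1L) %% 2L + 1L]
                stem <- names(ROLE_STEMS)[match(locus$role_truth[i],
                                                ROLE_STEMS)]
                fam <- Filter(function(f) f$type == donor && f$stem == stem,
                              world@families)[[1]]
                locus$seq[i] <- fam$msa[sample(heldOut, 1L)]
                locus$family[i] <- fam$name
                locus$type_truth[i] <- donor
            }
            locus
        }
    })
}

#' Write a fixture world to disk
#'
#' Emits one multi-FASTA per locus (genes in order), one aligned FASTA per
#' family, a truth-label TSV and a registry file, all consumable by the
#' other modules.
#'
#' @param world A [FixtureWorld-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeWorld <- function(world, dir) {
    stopifnot(is(world, "FixtureWorld"))
    dir.create(file.path(dir, "loci"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "families"), showWarnings = FALSE)
    truth <- do.call(rbind, lapply(names(world@loci), function(lid) {
        cbind(locus_id = lid, world@loci[[lid]], stringsAsFactors = FALSE)
    }))
    for (lid in names(world@loci)) {
        locus <- world@loci[[lid]]
        writeMultiFasta(data.frame(id = locus$id, description = "",
                                   seq = locus$seq, stringsAsFactors = FALSE),
                        file.path(dir, "loci", paste0(lid, ".faa")))
    }
    for (f in world@families) {
        writeMultiFasta(data.frame(id = paste0(f$name, "_s",
                                               seq_along(f$msa)),
                                   description = "", seq = f$msa,
                                   stringsAsFactors = FALSE),
                        file.path(dir, "families", paste0(f$name, ".afa")))
    }
    utils::write.table(truth[, c("locus_id", "id", "role_truth", "family",
                                 "type_truth")],
                       file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    saveRegistry(worldRegistry(world), file.path(dir, "world.registry"))
    invisible(dir)
}

#' Evaluate type recovery on a fixture world
#'
#' Classifies every locus of the world with a (typically train-on-half)
#' profile library: best assignments, majority-vote type call, and
#' closest-type ranking against a truth-derived registry. Scoring is
#' shared across loci through a sequence-level cache, so repeated held-out
#' sequences are scored once.
#'
#' @param world A [FixtureWorld-class].
#' @param library Profile library (default [worldProfileLibrary()]).
#' @param registry Reference registry (default [worldRegistry()]).
#' @param alpha,majority,threshold Pipeline parameters.
#' @return A `data.frame` with one row per locus: `locus_id`,
#'   `type_truth`, `called`, `status`, `confidence`, `rank1`,
#'   `rank1_correct`.
#' @export
evaluateTypeRecovery <- function(world, library = worldProfileLibrary(world),
                                 registry = worldRegistry(world),
                                 alpha = 0.5, majority = 0.5,
                                 threshold = NULL) {
    stopifnot(is(world, "FixtureWorld"))
    allSeqs <- unique(unlist(lapply(world@loci, `[[`, "seq"),
                             use.names = FALSE))
    recs <- data.frame(id = sprintf("u%05d", seq_along(allSeqs)),
                       description = "", index = seq_along(allSeqs) - 1L,
                       seq = allSeqs, stringsAsFactors = FALSE)
    hits <- searchLibrary(library, recs, threshold = threshold)
    bySeq <- assignBest(hits)
    rows <- lapply(names(world@loci), function(lid) {
        locus <- world@loci[[lid]]
        asg <- bySeq[match(locus$seq, allSeqs), , drop = FALSE]
        asg$query_id <- locus$id
        tc <- callType(asg, majority = majority)
        rk1 <- NA_character_
        if (any(asg$role != "NONE")) {
            fp <- makeFingerprint(asg, lid)
            rk1 <- rankClosest(fp, registry, k = 1L, alpha = alpha)$type[1]
        }
        data.frame(locus_id = lid, type_truth = locus$type_truth[1],
                   called = assignedType(tc), status = typingStatus(tc),
                   confidence = confidence(tc), rank1 = rk1,
                   rank1_correct = identical(rk1, locus$type_truth[1]),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
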