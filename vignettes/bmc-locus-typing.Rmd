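---
title: "Typing bacterial microcompartment loci with profile HMM fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing bacterial microcompartment loci with profile HMM fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmctyper)
```

## The problem

Bacterial microcompartment (BMC) shell proteins — pfam00936 hexamers
(BMC-H, the permuted BMC-H^p, the tandem-domain BMC-T^s/BMC-T^sp/BMC-T^dp)
and pfam03319 pentamers (BMC-P) — are diagnostic of BMC loci but so
homologous across functional types that generic annotation collapses them
onto a few well-studied systems. Reliable typing needs two signals
combined: *which* finely resolved protein families are present in a locus,
and *in what order* the genes occur. `bmctyper` scores ordered protein
sequences against a library of family-level profile HMMs, condenses each
locus into an ordered fingerprint of best-hit profile names, compares
fingerprints by a blended inventory/order similarity against reference
types, and calls the type by majority vote, flagging ambiguous (candidate
novel) and shell-free inputs.

The package trusts input order as gene order — a deliberate contract:
callers supply a multi-FASTA whose records are ordered as on the genome,
and no coordinates are parsed from headers.

## The scoring model

Each profile is a Plan7-style HMM: match states $M_1..M_L$ with
per-state emission distributions over the 20 standard amino acids, insert
states with a single shared emission vector, and delete states.
Parameters are estimated from an aligned family:

- **Match columns** are alignment columns with gap fraction $\le 0.5$
  (ties at exactly 0.5 included). Below one match column the alignment is
  rejected.
- **Emissions** are observed frequencies plus a pseudocount of $+1/20$
  per residue, renormalized; insert emissions pool all non-match columns.
- **Transitions** ($m\!\to\!m, m\!\to\!i, m\!\to\!d, i\!\to\!m,
  i\!\to\!i, d\!\to\!m, d\!\to\!d$ per state) are counted from each row's
  implied state path with $+1$ smoothing per transition. Plan7 has no
  $d\!\to\!i$/$i\!\to\!d$ edges; insert runs adjacent to a deletion count
  toward the deletion's direct transition, and the insert exit is counted
  as $i\!\to\!m$.

Estimation is deterministic and invariant to row order, and every
probability is strictly positive after pseudocounting.

### Local alignment topology and the bitscore

Scoring uses a *local* topology chosen to be simple enough to verify
exhaustively: uniform entry $1/L$ from the begin state into any match
state at any query position; a constant exit probability $p_E = 0.1$ from
every non-final match state ($p_E = 1$ from $M_L$), with the remaining
mass scaling the trained transitions; and flanking residues emitted by
the background, which cancel exactly against the null model. The reported
score is the forward log-odds bitscore

$$S(x) = \log_2 \frac{P(x \mid \text{profile})}{P(x \mid \text{background})},$$

computed in log space. The background defaults to uniform $1/20$
(overridable per profile); non-standard letters (B, J, O, U, X, Z) emit
the background in both numerator and denominator and therefore score
zero log-odds wherever they align.

Because the topology is a bona fide probabilistic model, the test suite
can check the dynamic program against an independent oracle that
enumerates *every* legal state path on small fixtures (profile length
$\le 3$, query length $\le 5$) and sums their odds directly; the two
agree to $10^{-9}$ relative. A Viterbi pass over the same topology gives
the single best path (always $\le$ the forward score) and its alignment
envelope. Tandem constructs are recognized by re-scoring the flanks of
the Viterbi envelope: each flank that clears the threshold on its own
contributes another domain, so two concatenated copies of a family
consensus report `n_domains = 2`. Tandem-domain *classification*
(BMC-T), however, is carried by profile identity — T-profiles are
trained on full-length tandem sequences — with `n_domains` kept as
metadata only, and only one best profile is reported per protein,
mirroring the one-label-per-gene locus diagram.

**Acceptance threshold.** Hits require $S \ge 20$ bits by default,
configurable per profile or globally per run. The threshold is a
deliberate simplification: a deterministic bit cutoff instead of
E-value calibration, which would require Gumbel parameter fitting that
the scoring contract does not need. At 20 bits a random-sequence hit
needs roughly a million-to-one odds ratio, far beyond anything the
shuffled-sequence controls produce, while genuine family members in the
synthetic worlds score over 100 bits.

## Naming, roles, colors

Profiles are named `<ROLE>_<color>` (`H_azure`, `P_amber`) or, for
type-specific profiles trained on sequences from a single BMC type,
`<TYPE>__<ROLE>_<color>` (`SPU1__H_azure`) with `__` reserved. Role stems
map to the fixed diagram colors: yellow BMC-P, blue BMC-H/BMC-H^p, light
blue BMC-T^s/BMC-T^sp, teal BMC-T^dp, purple signature enzyme, orange
regulator, red AldDh, green AlcDh, magenta PTAC, black other conserved,
grey unassigned. Unknown stems degrade gracefully to `OTHER_CONSERVED`.

## Fingerprints and the similarity score

The fingerprint of a locus is the ordered list of assigned profile
names. Similarity between fingerprints $f_1, f_2$ is

$$S = \alpha J + (1 - \alpha) O, \qquad \alpha = 0.5,$$

with $J$ the Jaccard index of the label sets and $O$ the order
component: the count of aligned equal labels maximized over all integer
offsets *and both orientations* of $f_2$, divided by
$\max(|f_1|, |f_2|)$. Design notes, since the choice of formalization
was open:

- The equal blend $\alpha = 0.5$ treats component inventory and gene
  order as equally informative; either signal alone is insufficient
  (paralog-rich loci share inventories across related types, and order
  alone ignores content).
- Normalizing by the longer fingerprint penalizes unmatched positions on
  either side, so a fragment never scores 1 against a full locus.
- The reversed orientation is searched because operons occur on either
  strand; with orientation search disabled the reversed triple
  `[A,B,C]` vs `[C,B,A]` drops from 1 to $2/3$ (inventory 1, best
  forward overlap $1/3$).

The score is symmetric, bounded in $[0,1]$, and 1 exactly on identical
fingerprints; the test suite checks it against a brute-force
anchor-enumeration oracle on random pairs. Reference ranking reports each
registry type's best-matching example, the top five by default; ties
break lexicographically so reports are byte-reproducible. Locus
clustering is single linkage (connected components at similarity
$\ge 0.6$), delegated to `stats::hclust`, with cluster labels ordered by
smallest member locus id.

## The type call

All typed assignments vote — shell proteins and enzymes alike, since
type-specific enzyme profiles are as diagnostic as shell ones (a
shell-only vote mode remains available as a flag). With votes $v$, modal
count $m$:

- `assigned` iff a *unique* modal type has $m / \sum v \ge 0.5$
  (confidence $= m/\sum v$);
- `ambiguous` otherwise — ties are always ambiguous, and a six-way
  one-vote-each split yields confidence $1/6$;
- `no_shell` when no shell-role assignment exists at all, regardless of
  enzyme votes.

Ambiguous calls additionally list the types of any signature-enzyme
assignments: in mixed-shell loci the signature enzyme is often the best
functional hint, so the report surfaces it separately rather than letting
it drown in the vote table.

## Candidate loci in whole proteomes

The shell-only scan restricts the library to shell profiles (anything
else is rejected) and returns shell assignments plus per-class counts.
Each hit then seeds a window of 12 genes on each side — the convention
under which the reference loci were originally collected — clipped to the
proteome; overlapping *or touching* windows merge (a single operonic run
should never split), implemented with `IRanges::reduce`. Indices are
0-based internally and 1-based in reports. Whether satellite loci should
merge with main loci is genuinely undecidable without coordinates; each
merged interval is reported as one candidate locus and satellite
resolution is left to the user.

## The reference registry

`inst/extdata/bmc_types.registry` enumerates the 68 BMC types/subtypes of
the published classification scheme (SPU1–6, EUT, PDU, GRM, carboxysome
CSO/CCM families, and the rest of the scheme) in a documented
line-oriented text format (`TYPE`/`DESC`/`INV`/`FP`/`SEQ`/`END`).
The shipped example fingerprints are *synthetic placeholders* generated
under the profile naming convention — stand-ins until users load real
loci — which is why ranking tests against real data use registries built
from fixture truth instead. Load/save round-trips exactly. Per-type
sequence summaries reduce to count, length min/mean/max and isoelectric
point min/mean/max (pKa bisection via `seqinr::computePI`); sequence
logos and hosted pages are out of scope, as is any network access —
SWISS-MODEL integration emits a deterministic submission URL only.

## The synthetic fixture generator

`generateWorld(seed, ...)` is first-class, tested code, not a test
afterthought. Per type and role it creates a family of `familySize >= 3`
sequences (the floor below which alignments are too thin to train on):
a conserved random motif of 48 residues with per-position substitution
noise of 10%, flanked by 8-residue per-sequence random spacers. Rows are
equal length, so each family is its own training alignment. Loci repeat
the type's roles in a per-type canonical order (rotated to lead with a
shell role, so every locus contains one), draw every gene from the
*held-out back half* of its family — profiles are trained on the front
half, keeping train/test leakage structurally impossible — insert 20%
untyped bystander genes, and apply up to two adjacent swaps. One seeded
Mersenne-Twister stream drives everything; the caller's RNG state is
saved and restored, and regeneration is bit-identical.

Defaults (10 types, 8 loci per type, 20-gene loci) are the reference
conditions used by the recovery suite and the acceptance script; the
smaller worlds in unit tests (3 types, 12-gene loci) keep the default
test run fast. These worlds emulate what matters for the pipeline's
logic — family conservation vs. background, paralogy, gene-order noise,
bystanders — and deliberately not what doesn't: no phylogenetic
correlation between families, no shared domains across types, no indel
evolution inside motifs. Passing the 95%-recovery bar therefore shows the
machinery is sound, not that real metagenome loci will type at that
accuracy; real families are harder precisely because they share ancestry.

### Corruption modes

`corruptLocus()` produces the failure inputs the status taxonomy exists
for: `shuffle` permutes gene order (votes are order-free, so the vote
table is unchanged); `drop_shell` removes all shell genes (`no_shell`).
`mix_types` emulates the mixed-type pattern of candidate novel loci: it
replaces just over half of the *typed* genes — `floor(t/2) + 1` of them,
same-role replacements cycled across two donor types — so the original
type keeps fewer than half the votes and no donor reaches a majority,
guaranteeing `ambiguous` under the default vote rule. Replacing only
shell genes cannot do this whenever typed enzymes remain (the original
type would always retain at least half), so the corruption operates on
the typed complement; this is the package's definition of a mixed locus.

## Numerical choices and degenerate inputs

- All path sums run in natural-log space with a guarded log-sum-exp
  (fast paths for $-\infty$ and differences beyond 36); scores are
  converted to bits once at the end.
- $p_E = 0.1$ is a fixed model constant, not trained; it keeps entry/exit
  mass spread over match states without swamping the trained transitions.
- HMMER3 imports floor zero probabilities (`*` entries) at $10^{-8}$ and
  renormalize, and average per-state insert emissions into the shared
  vector, because the container guarantees strictly positive
  probabilities and one insert distribution.
- The native library format serializes doubles at `%.17g`, so
  write/read round-trips are exact.
- Ties break lexicographically everywhere (best hit, closest types,
  cluster labels), making every report deterministic byte for byte.
- Degenerate inputs (empty alignments or sequences, ragged rows, gap-only
  alignments, duplicate FASTA ids, empty registries) are rejected with
  classed conditions naming the offending record, row or line; the CLI
  maps input errors to exit 2, empty-but-well-formed analyses to 3, and
  anything else to 4.

## Problem sizes in the test suite

The recovery and corruption suites run on the reference world (10 types,
60 families, 80 loci of 20 genes; roughly 30,000 forward evaluations
through a per-run sequence cache); the oracle suites run on hundreds of
profile/query and fingerprint pairs small enough for exhaustive
enumeration. The full suite and the acceptance script each complete in a
few minutes on a single core.

## Known limitations

- The bit threshold is uncalibrated; no E-values are reported, so scores
  are comparable within a library but not across databases.
- One profile per protein: secondary domains surface only through
  `n_domains`, and fused novel architectures will take the label of the
  best-scoring half.
- The similarity formalization (equal blend, max-length normalizer,
  orientation search) is a documented stand-in for the original
  cross-correlation, whose exact weights are not recoverable; thresholds
  may need recalibration if that definition is ever adopted.
- Input order is trusted as genome order; shuffled proteomes silently
  produce meaningless fingerprints (the type vote, being order-free,
  survives).
- The shipped registry's example fingerprints are synthetic placeholders;
  closest-type rankings against it are structural until real reference
  loci are loaded.
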