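---
title: "CypMine: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CypMine: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CypMine)
```

## The problem

Cytochrome P450 monooxygenases (CYPs/P450s) are heme-thiolate enzymes
that contribute heavily to secondary-metabolite chemistry in
bacteria, most famously in *Streptomyces*. Comparative genome-mining
studies of P450 complements follow a well-worn recipe:

1. collect candidate hit proteins from each proteome,
2. keep the ones that look like real, intact P450s,
3. name them under the standard CYP nomenclature by percent identity
   to named reference P450s,
4. intersect their genes with predicted secondary-metabolite
   biosynthetic gene clusters (BGCs), and
5. roll the cohort up into comparative tables (totals, averages,
   percentages, presence/absence heat-map matrices).

CypMine implements steps 2-5 as tested, deterministic code, and adds
a synthetic-cohort generator so that the whole chain can be validated
against planted truth without downloading a single genome. Candidate
*discovery* (InterPro/profile searches) and BGC *detection*
(antiSMASH) are out of scope: the package consumes their outputs
(protein FASTA, GFF3 gene coordinates, a per-cluster summary TSV).

## Motif triage

Bacterial P450s carry two short conserved signatures: the K-helix
**EXXR** salt bridge and the heme-loop **CXG** around the axial
cysteine. Triage classifies every hit protein by these motifs:

* both motifs present → `COMPLETE` (flows on to classification);
* exactly one motif → `PSEUDO` (both-present takes precedence, so
  "one motif" is read as *exactly* one);
* neither motif and shorter than `fragmentMaxLen` → `FRAGMENT`;
* neither motif at or above that length → `NON_CANDIDATE`
  (a false-positive hit rather than a truncated P450).

Scans report **every** overlapping occurrence, ascending, 0-based.
The wildcard positions match any letter (including `X`); only the
anchor letters E/R and C/G must match exactly. The motifs are
searched over the full sequence and no order between them is
required, since typical mining protocols state neither a positional
window nor an order.

`fragmentMaxLen` defaults to **300 residues**. "Short" is not
standardised anywhere; a typical bacterial P450 runs ~400 residues,
so 300 is a conservative split between plausibly truncated hits and
unrelated long proteins. It is a plain argument, and raising it can
only move proteins from `NON_CANDIDATE` to `FRAGMENT`, never the
reverse (a tested monotonicity property).

## Percent identity and the nomenclature thresholds

The CYP nomenclature assigns a query to the *family* of its best
named homolog at **greater than 40%** identity and to its
*subfamily* at **greater than 55%**; below that the query founds a
new family. CypMine reads both thresholds strictly: a best identity
of exactly 55.0 stays at family level and exactly 40.0 founds a new
family (covered by a dedicated boundary test with planted identities
of exactly 40.0 and 55.0).

Identity itself is defined as

\[
\mathrm{PID} = 100 \times \frac{\text{identical columns}}
                              {\text{all alignment columns}}
\]

over an **optimal global (Needleman-Wunsch) alignment** with
BLOSUM62, affine gap penalties (open 10, extend 1; a gap run of
length $L$ costs $10 + L$), end gaps penalised, and gap columns
counted in the denominator. Historical P450 annotation pipelines
used local BLAST identities with unstated parameters; a global,
fully-parameterised definition is deterministic, reproducible and
slightly stricter, and that divergence is deliberate. A local
(Smith-Waterman) scheme is available via
`ScoringScheme(type = "local")` for sensitivity analysis.

Alignments are computed by `Biostrings::pairwiseAlignment()`. Its
traceback is deterministic; where several alignments are co-optimal
the identity of the returned one is asserted (in the test suite) to
match one of the co-optimal alignments found by exhaustive
enumeration on short pairs. Ties between equally good *references*
break to the lexicographically smallest reference name.

### Placeholder names

Software cannot mint committee-issued CYP numbers, so:

* `NEW_FAMILY` queries receive `NEWF001`, `NEWF002`, ... in order of
  first appearance after sorting by (species, protein). Queries
  sharing more than 40% mutual identity are merged into one
  placeholder family by **single linkage** — the natural reading of
  "assign them to the same new family", though any linkage rule is
  defensible; within a placeholder family the 55% rule partitions
  queries into lettered subfamilies (`NEWF001A`, ...).
* `FAMILY`-level queries get per-family new-subfamily placeholders
  (`CYP105-newSF1`, ...), again merged by single linkage over 55%.

The allocation depends on row order, so unsorted input is refused
rather than silently renumbered.

## BGC membership and linkage

A P450 gene belongs to a cluster when both lie on the same species
and contig and their 1-based inclusive intervals share **at least
one base**. Mining protocols typically state only that clusters
were checked for P450 content, without defining an overlap rule;
one shared base is the weakest defensible reading, and full
containment is available via `overlap = "contained"`. Strand is ignored throughout. A P450
inside two overlapping clusters yields two memberships, one per
(P450, cluster) pair — whether historical tallies counted such a
P450 once or twice is unstated, so the per-pair convention is
declared and the distinct-P450 count is used wherever a percentage
of P450s is reported.

Hybrid clusters (several type labels, e.g. `bacteriocin;NRPS`)
contribute one count *per label* to the family-by-type linkage table
and to the per-type cluster tally; this preserves per-type totals
without inventing a primary-type rule.

Gene-to-protein matching requires `gene_id == protein_id`; how
mining pipelines matched identifiers across genome-portal files is
never stated, so the requirement is explicit rather than guessed.

## Cohort arithmetic

Printed comparative tables in this literature use two different
integer conventions, and only one combination is consistent with
every cell that can be checked: **averages round half away from
zero** (5460/203 = 26.90 → 27; 4457/144 = 30.95 → 31; 507/128 =
3.96 → 4) while **percentages truncate** (1231/5460 = 22.54 → 22;
204/1784 = 11.43 → 11). One known cell (27/341 = 7.92 printed as 8)
contradicts truncation; it is flagged here and deliberately not
matched. `roundedMean()` and `truncatedPercent()` implement the two
conventions exactly and are property-tested against integer rational
arithmetic.

Other conventions:

* "number of P450s" always means `COMPLETE` triage calls — pseudo
  P450s and fragments are excluded from all further analysis;
* modal counts break ties to the smallest value;
* BGC averages and the in-BGC percentage are computed over the
  BGC-analyzed species only, with numerator and denominator always
  drawn from the same species set (cohorts often BGC-analyse a
  subset of the species); both P450 totals are exposed so either
  denominator can be inspected;
* the presence matrix encodes presence as `3` and absence as `-3`,
  the conventional encoding for red/green profile heat-map export;
  rendering and clustering of the heat-map are presentation concerns
  and out of scope.

## The synthetic-cohort generator

`makeCohort()` manufactures the full input bundle — reference
database, per-species proteomes, gene coordinates, cluster table —
together with the truth table it was built from. Everything is a
deterministic function of the `SimSpec` seed, and
`writeCohortBundle()` emits byte-identical files across runs.

What it emulates:

* references with valid CYP names (families numbered from 9001 to
  avoid any collision with real names), planted motifs, controlled
  pairwise identities (cross-family < 35%, subfamily representatives
  at 45-54% to their family seed);
* complete P450s derived from references at planted identities,
  pseudo-P450s with exactly one motif, short fragments and long
  non-candidates with none;
* a BGC layout where a planted fraction of complete-P450 genes sit
  inside clusters (one cluster per in-BGC gene plus empty clusters),
  with hybrid type labels and occasional known-cluster annotations.

Identity targeting substitutes random non-anchor positions and
re-verifies with the package's own aligner, adjusting the
substitution count from the measured error (accept/reject within ±2
points), because gapped global identity is not a closed-form
function of the substitution count. Planted queries are additionally
verified to have their planted reference as the strict best hit, and
cohort-level registries keep new-family queries mutually below 37%
and family-level queries of one family mutually below 52%,
regenerating on failure — so the truth table is correct by
construction, not by hope.

Identity targets must avoid the bands **[37, 43]** and **[52, 58]**
around the two thresholds (`stressThresholds = TRUE` lifts this for
deliberate boundary tests), which combined with the ±2 targeting
tolerance keeps every planted label at least 3 points clear of a
threshold and makes recovery tests deterministic.

Default study conditions: 5 species × (12 complete + 1 pseudo + 2
fragments + 1 non-candidate), a 3-family × 2-subfamily reference
database, planted level mix of 60% subfamily / 25% family / 15% new
family, 6 clusters per species with 20% of complete-P450 genes in
clusters. These are scaled-down analogues of real cohorts (tens of
P450s per species, a few percent of hits being pseudo/fragment, a
minority of P450s inside clusters), sized so that a full end-to-end
run takes well under a minute; the same generator accepts larger
specs unchanged.

What it does **not** emulate — and hence what passing tests do not
show about real data: sequences are uniform over the 20 residues
with planted motifs, not HMM-sampled P450s, so real-world hazards
like compositional bias, low-complexity regions, domain fusions or
genuinely ambiguous mid-identity homology are absent; gene layouts
are regular and non-overlapping; cluster boundaries are exact. The
synthetic cohorts validate the *logic* of triage, classification,
membership and arithmetic, not the biological adequacy of the 40/55
identity rule itself.

## Numerical choices and degenerate inputs

* Alignment scores are integers (BLOSUM62, integer penalties), so
  optimality comparisons in the oracle tests are exact.
* Zero-length sequences are rejected by the aligner; empty FASTA
  files, empty proteomes, empty membership sets and empty reference
  subsets all return empty, well-typed results rather than errors,
  except where the operation is undefined (modal count or range of
  nothing, summary of zero species, division by zero), which error
  loudly.
* Coordinates are 1-based inclusive (GFF3 convention) everywhere;
  readers never mutate them, and any 0-based input must be converted
  at the boundary.
* Subfamily letters are capped at two when parsing (the longest in
  real usage, e.g. `CYP107FH5`); longer runs are rejected rather
  than guessed. Placeholder subfamilies beyond 26 extend to double
  letters instead of failing.

## A worked example

```{r example, eval = FALSE}
cohort <- makeCohort(simSpec(seed = 42))
res <- runCohortPipeline(cohort)

res$summary                 # equals cohort$truthSummary exactly
familyTally(res$assignments)
conservedFamilies(res$profiles)
presenceMatrix(res$profiles)[, 1:4]
familyBgcLinkage(res$memberships)
bgcTypeTally(res$memberships, cohort$clusters)
```

The same stages run unchanged on real inputs read with
`readProteomeFasta()`, `readReferenceFasta()`, `readGffGenes()` and
`readClusterTable()`.

## Known limitations

* Classification is purely best-hit percent identity; phylogeny-aware
  annotation can detect similarity cues beyond a fixed cutoff and is
  deliberately not implemented.
* Reference databases are trusted as named; no attempt is made to
  detect mis-named references.
* E-values, coverage filters and profile searches are out of scope;
  queries are assumed to already be P450 candidates.
* The BGC table is consumed as given; cluster boundary quality is
  whatever the upstream detector produced.
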