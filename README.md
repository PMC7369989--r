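# CypMine

Comparative genome mining of cytochrome P450 monooxygenases
(CYPs/P450s) in bacterial proteomes, for people who study the P450
complements of *Streptomyces* and related genera and their role in
secondary-metabolite biosynthesis.

P450 mining pipelines in this field share four stages, and CypMine
implements all of them as tested, deterministic R code:

1. **Motif triage.** Candidate hit proteins are screened for the two
   conserved P450 signatures — the K-helix **EXXR** motif and the
   heme-loop **CXG** motif. Proteins with both motifs are complete
   P450s; with exactly one, pseudo-P450s; with neither, fragments
   (short) or non-candidates (long). Only complete P450s go further.
2. **Family/subfamily assignment.** Each complete P450 is compared
   against a database of named reference P450s by percent identity
   under an optimal global alignment (BLOSUM62, affine gaps 10/1,
   gap columns in the denominator). Following the standard CYP
   nomenclature rule, identity strictly above 55% to the best hit
   puts the query in that reference's subfamily, strictly above 40%
   in its family, and at or below 40% the query founds a new family
   (placeholder names `NEWF001`, ..., merged by single linkage over
   the >40% relation).
3. **BGC linkage.** P450 genes are intersected with
   secondary-metabolite biosynthetic gene cluster (BGC) intervals
   (antiSMASH-style summary tables); family-by-cluster-type linkage
   and per-type tallies are tabulated.
4. **Cohort statistics.** Per-species profiles, conserved families,
   family tallies, subfamily diversity, 3/-3 presence matrices for
   heat-map export, and the per-genus comparative summary (averages
   rounded half away from zero, percentages truncated — the two
   integer conventions used by printed tables in this literature).

A first-class synthetic-cohort generator (`makeCohort()`) plants
proteomes, reference databases and BGC layouts with known truth so
every stage can be validated end to end with no downloads. See the
methods vignette (`vignettes/cypmine-methods.Rmd`) for the design
decisions and their rationale.

## A worked example

```r
library(CypMine)

cohort <- makeCohort(simSpec(seed = 42))   # 5 species x 12 P450s
res <- runCohortPipeline(cohort)           # triage -> classify -> link
res$summary
#>   n_species total_p450s n_families n_subfamilies dominant_family avg_p450s
#> 1         5          60          8            26         CYP9001        12
#>   n_bgc_species total_bgcs avg_bgcs total_p450s_bgc_species total_p450s_in_bgcs
#> 1             5         30        6                      60                  10
#>   pct_p450s_in_bgcs
#> 1                16
```

The cohort has 60 complete P450s in 8 families (3 planted reference
families plus 5 new-family placeholders), 30 clusters, and 10 P450s
inside clusters — `floor(100 * 10/60)` prints as 16%. The summary
equals the generator's truth table exactly
(`identical(res$summary, cohort$truthSummary)` is `TRUE`).

```r
head(familyTally(res$assignments), 3)
#>   family_label  n
#> 1      CYP9001 20
#> 2      CYP9002 20
#> 3      CYP9003 15

conservedFamilies(res$profiles)
#> [1] "CYP9001" "CYP9002" "CYP9003"

bgcTypeTally(res$memberships, cohort$clusters)
#>    type_label n_clusters
#> 1 bacteriocin          6
#> 2       T1PKS          2
#> 3       T3PKS          2
#> 4     terpene          2
```

Real data flow through the same stages via `readProteomeFasta()`,
`readReferenceFasta()`, `readGffGenes()` and `readClusterTable()`:

```r
aa  <- readProteomeFasta("species1.faa", "species1")
tri <- triageProteome(aa)
asg <- classifyProteome(completeP450s(aa, tri$calls),
                        readReferenceFasta("refs.faa"))
mem <- linkP450s(asg, readGffGenes("species1.gff3", "species1"),
                 readClusterTable("clusters.tsv"))
```

The package also ships, under `inst/extdata/`, the transcribed
per-species P450 counts of a published 203-species *Streptomyces*
survey and the comparative totals for four bacterial genera, so the
cohort arithmetic can be exercised on real printed numbers
(`streptomycesP450Counts()`, `cohortTotals()`, `newFamilyTokens()`).

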