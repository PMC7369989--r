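## Bundled plain-text reference tables: the per-species P450 counts
## of a 203-species Streptomyces survey, the comparative per-genus
## totals for Streptomyces / Mycobacterium / Bacillus /
## Cyanobacteria, and the enumerated list of newly founded P450
## family names.  These ship with the package so the comparative
## arithmetic can be reproduced without any download.

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "CypMine",
                      mustWork = TRUE)
  path
}

#' Per-species Streptomyces P450 counts
#'
#' Per-species complete-P450, family and subfamily counts for a
#' 203-species \emph{Streptomyces} survey.
#'
#' @return data.frame with columns \code{species}, \code{n_p450},
#'   \code{n_families}, \code{n_subfamilies}.
#' @examples
#' counts <- streptomycesP450Counts()
#' modalCount(counts$n_p450)   # 19
#' @export
streptomycesP450Counts <- function() {
  read.delim(.extdata("streptomyces_p450_counts.tsv"),
             stringsAsFactors = FALSE)
}

#' Comparative per-genus P450 and BGC totals
#'
#' Species, P450 and BGC totals for the four bacterial cohorts
#' (\emph{Streptomyces}, \emph{Mycobacterium}, \emph{Bacillus},
#' Cyanobacteria).  \code{n_bgc_species} is the number of species
#' whose genomes went through BGC analysis, which can be smaller
#' than \code{n_species}.
#'
#' @return data.frame with columns \code{cohort}, \code{n_species},
#'   \code{n_p450}, \code{n_bgc_species}, \code{n_bgc},
#'   \code{n_p450_in_bgc}.
#' @export
cohortTotals <- function() {
  read.delim(.extdata("cohort_totals.tsv"), stringsAsFactors = FALSE)
}

#' Newly founded P450 family name tokens
#'
#' The enumerated names under which new P450 families were founded
#' in the 155 newly mined \emph{Streptomyces} genomes, as tokens for
#' \code{\link{parseCypName}}.
#'
#' @return character vector of CYP name tokens.
#' @examples
#' length(unique(familyLabel(parseCypName(newFamilyTokens()))))  # 38
#' @export
newFamilyTokens <- function() {
  readLines(.extdata("new_p450_families.txt"))
}
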