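## Cohort roll-up statistics: the per-genus comparative table, the
## per-species profiles and the presence/absence matrix export.
##
## Printed cohort tables in this field use two different integer
## conventions: averages are rounded half away from zero while
## percentages are truncated toward zero.  Both are exposed as exact
## integer operations rather than format-time conveniences.

#' Integer average, rounded half away from zero
#'
#' \code{total / n} rounded half away from zero (so 26.90 -> 27,
#' 30.95 -> 31, 3.5 -> 4, -3.5 -> -4).
#'
#' @param total numerator count.
#' @param n denominator count, at least 1.
#' @return integer.
#' @examples
#' roundedMean(5460, 203)  # 27
#' roundedMean(4457, 144)  # 31
#' @export
roundedMean <- function(total, n) {
  stopifnot(length(total) == 1L, length(n) == 1L)
  if (n < 1) stop("denominator must be at least 1")
  x <- total / n
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Integer percentage, truncated toward zero
#'
#' \code{floor(100 * part / total)} for non-negative counts.
#'
#' @param part numerator count, at most \code{total}.
#' @param total denominator count, at least 1.
#' @return integer in [0, 100].
#' @examples
#' truncatedPercent(1231, 5460)  # 22
#' truncatedPercent(204, 1784)   # 11
#' @export
truncatedPercent <- function(part, total) {
  stopifnot(length(part) == 1L, length(total) == 1L)
  if (total < 1) stop("denominator must be at least 1")
  if (part > total) stop("part exceeds total")
  as.integer(floor(100 * part / total))
}

#' Most frequent count
#'
#' Ties break to the smallest value.
#'
#' @param values non-empty vector of counts.
#' @return the modal value as an integer.
#' @examples
#' modalCount(c(1, 2, 2, 3))  # 2
#' modalCount(c(1, 1, 2, 2))  # 1 (tie-break: smallest)
#' @export
modalCount <- function(values) {
  if (!length(values)) stop("empty input")
  ux <- sort(unique(values))
  counts <- vapply(ux, function(v) sum(values == v), integer(1))
  as.integer(ux[which.max(counts)])
}

#' Range of counts
#'
#' @param values non-empty vector of counts.
#' @return named integer vector \code{c(min = ..., max = ...)}.
#' @export
countRange <- function(values) {
  if (!length(values)) stop("empty input")
  c(min = as.integer(min(values)), max = as.integer(max(values)))
}

#' Per-species profiles
#'
#' One row per species: complete-P450 count, family and subfamily
#' label sets, the number of distinct P450s with at least one BGC
#' membership, and the species' cluster count.  A P450 sitting in two
#' clusters counts once toward \code{n_in_bgc}.
#'
#' @param assignments classification results (see
#'   \code{\link{classifyProteome}}).
#' @param memberships BGC memberships (see \code{\link{linkP450s}});
#'   may be \code{NULL} when no cluster data exist.
#' @param clusters cluster \code{GRanges}; may be \code{NULL}.
#' @param bgcSpecies species whose genomes went through BGC analysis;
#'   defaults to the species present in \code{clusters}.  Species
#'   outside this set get \code{bgc_analyzed = FALSE} and do not
#'   enter BGC averages.
#' @return a \code{DataFrame} with columns \code{species_id},
#'   \code{n_p450}, \code{family_labels}, \code{subfamily_labels}
#'   (\code{CharacterList}s), \code{n_in_bgc}, \code{n_bgc},
#'   \code{bgc_analyzed}.
#' @export
speciesProfiles <- function(assignments, memberships = NULL,
                            clusters = NULL, bgcSpecies = NULL) {
  if (is.null(bgcSpecies))
    bgcSpecies <- if (!is.null(clusters) && length(clusters))
      unique(clusters$species_id) else character(0)
  species <- sort(unique(c(assignments$species_id, bgcSpecies)))
  perSpecies <- function(sp) {
    a <- assignments[assignments$species_id == sp, , drop = FALSE]
    nInBgc <- if (is.null(memberships) || !nrow(memberships)) 0L
      else length(unique(
        memberships$protein_id[memberships$species_id == sp]))
    nBgc <- if (is.null(clusters)) 0L
      else sum(clusters$species_id == sp)
    list(n_p450 = nrow(a),
         fams = sort(unique(a$family_label)),
         subs = sort(unique(a$subfamily_label)),
         n_in_bgc = nInBgc, n_bgc = nBgc)
  }
  rows <- lapply(species, perSpecies)
  DataFrame(
    species_id = species,
    n_p450 = vapply(rows, `[[`, integer(1), "n_p450"),
    family_labels = CharacterList(lapply(rows, `[[`, "fams")),
    subfamily_labels = CharacterList(lapply(rows, `[[`, "subs")),
    n_in_bgc = vapply(rows, `[[`, integer(1), "n_in_bgc"),
    n_bgc = vapply(rows, `[[`, integer(1), "n_bgc"),
    bgc_analyzed = species %in% bgcSpecies)
}

#' Species-by-family presence matrix
#'
#' Incidence matrix encoded 3 for presence and -3 for absence, the
#' standard encoding for red/green P450 profile heat-map export.
#' Species order follows \code{profiles}; family order defaults to
#' the sorted union of all observed families.
#'
#' @param profiles result of \code{\link{speciesProfiles}}.
#' @param familyOrder column order; must cover every family observed
#'   in \code{profiles}.
#' @return integer matrix with values in {3, -3}, species as rows.
#' @export
presenceMatrix <- function(profiles, familyOrder = NULL) {
  used <- unique(unlist(profiles$family_labels, use.names = FALSE))
  if (is.null(familyOrder)) familyOrder <- sort(used)
  missing <- setdiff(used, familyOrder)
  if (length(missing))
    stop("familyOrder is missing observed families: ",
         paste(missing, collapse = ", "))
  m <- matrix(-3L, nrow = nrow(profiles), ncol = length(familyOrder),
              dimnames = list(profiles$species_id, familyOrder))
  for (i in seq_len(nrow(profiles)))
    m[i, familyOrder %in% profiles$family_labels[[i]]] <- 3L
  m
}

#' Cohort-wide family member tally
#'
#' @param assignments classification results.
#' @return data.frame with \code{family_label} and \code{n}, ordered
#'   by decreasing count then name; counts sum to the number of
#'   assignments.
#' @export
familyTally <- function(assignments) {
  if (!nrow(assignments))
    return(data.frame(family_label = character(0), n = integer(0)))
  tab <- table(assignments$family_label)
  out <- data.frame(family_label = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$family_label), ]
  rownames(out) <- NULL
  out
}

#' Families conserved across a cohort
#'
#' @param profiles result of \code{\link{speciesProfiles}} with at
#'   least one row.
#' @return character vector of families present in every species.
#' @export
conservedFamilies <- function(profiles) {
  if (!nrow(profiles)) stop("no species profiles")
  sort(Reduce(intersect, as.list(profiles$family_labels)))
}

#' Subfamily diversity within families
#'
#' @param assignments classification results.
#' @return a list with \code{byFamily} (per family: number of
#'   distinct subfamilies and of members) and \code{bySubfamily}
#'   (member counts per subfamily), both ordered by decreasing count.
#' @export
subfamilyDiversity <- function(assignments) {
  if (!nrow(assignments))
    return(list(
      byFamily = data.frame(family_label = character(0),
                            n_subfamilies = integer(0),
                            n_members = integer(0)),
      bySubfamily = data.frame(family_label = character(0),
                               subfamily_label = character(0),
                               n_members = integer(0))))
  bySub <- aggregate(
    list(n_members = rep(1L, nrow(assignments))),
    assignments[c("family_label", "subfamily_label")], sum)
  byFam <- aggregate(
    cbind(n_subfamilies = rep(1L, nrow(bySub)),
          n_members = bySub$n_members),
    list(family_label = bySub$family_label), sum)
  byFam <- byFam[order(-byFam$n_subfamilies, -byFam$n_members,
                       byFam$family_label), ]
  bySub <- bySub[order(-bySub$n_members, bySub$family_label,
                       bySub$subfamily_label), ]
  rownames(byFam) <- rownames(bySub) <- NULL
  list(byFamily = byFam, bySubfamily = bySub)
}

#' Cohort summary
#'
#' The per-genus comparative roll-up: species and P450 totals, family
#' and subfamily counts, the dominant family, rounded averages and
#' the truncated percentage of P450s that sit in BGCs.  BGC averages
#' and the percentage are computed over the BGC-analyzed species only
#' (numerator and denominator always come from the same species set;
#' both P450 totals are exposed).
#'
#' @param profiles result of \code{\link{speciesProfiles}}.
#' @param assignments classification results.
#' @param memberships BGC memberships (see \code{\link{linkP450s}}).
#' @return a one-row data.frame with columns \code{n_species},
#'   \code{total_p450s}, \code{n_families}, \code{n_subfamilies},
#'   \code{dominant_family}, \code{avg_p450s}, \code{n_bgc_species},
#'   \code{total_bgcs}, \code{avg_bgcs},
#'   \code{total_p450s_bgc_species}, \code{total_p450s_in_bgcs},
#'   \code{pct_p450s_in_bgcs}.
#' @export
cohortSummary <- function(profiles, assignments, memberships = NULL) {
  if (!nrow(profiles)) stop("no species profiles")
  if (!is.null(memberships) && nrow(memberships)) {
    orphan <- setdiff(memberships$protein_id, assignments$protein_id)
    if (length(orphan))
      stop("memberships reference unknown proteins: ",
           paste(head(orphan, 5), collapse = ", "))
  }
  fams <- unique(unlist(profiles$family_labels, use.names = FALSE))
  subs <- unique(unlist(profiles$subfamily_labels, use.names = FALSE))
  tally <- familyTally(assignments)
  bgc <- profiles[profiles$bgc_analyzed, , drop = FALSE]
  totalBgcs <- sum(bgc$n_bgc)
  totalInBgc <- sum(bgc$n_in_bgc)
  totalP450Bgc <- sum(bgc$n_p450)
  data.frame(
    n_species = nrow(profiles),
    total_p450s = sum(profiles$n_p450),
    n_families = length(fams),
    n_subfamilies = length(subs),
    dominant_family = if (nrow(tally)) tally$family_label[1]
                      else NA_character_,
    avg_p450s = roundedMean(sum(profiles$n_p450), nrow(profiles)),
    n_bgc_species = nrow(bgc),
    total_bgcs = totalBgcs,
    avg_bgcs = if (nrow(bgc)) roundedMean(totalBgcs, nrow(bgc)) else 0L,
    total_p450s_bgc_species = totalP450Bgc,
    total_p450s_in_bgcs = totalInBgc,
    pct_p450s_in_bgcs = if (totalP450Bgc > 0)
      truncatedPercent(totalInBgc, totalP450Bgc) else 0L,
    stringsAsFactors = FALSE)
}
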