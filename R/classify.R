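## Family/subfamily assignment under the nomenclature thresholds.
##
## A query is compared against every named reference; the best hit
## decides the assignment.  Strictly greater than 55% identity puts
## the query in the best hit's subfamily, strictly greater than 40%
## in its family (with a new-subfamily placeholder), and at or below
## 40% the query founds a new family.  Committee-issued CYP numbers
## cannot be minted by software, so new families receive NEWFxxx
## placeholders, merged by single linkage over the >40% relation.

#' Default nomenclature thresholds
#'
#' Strict lower bounds: identity must exceed 40 to share a family and
#' exceed 55 to share a subfamily; exactly 40 founds a new family and
#' exactly 55 stays at family level.
#'
#' @export
cypThresholds <- c(family = 40, subfamily = 55)

.levelFromIdentity <- function(identity, thresholds = cypThresholds) {
  ifelse(identity > thresholds[["subfamily"]], "SUBFAMILY",
         ifelse(identity > thresholds[["family"]], "FAMILY",
                "NEW_FAMILY"))
}

#' Assign one query protein to a CYP family/subfamily
#'
#' @param query a single amino-acid sequence (character or
#'   \code{AAString}).
#' @param refdb a non-empty \code{\linkS4class{ReferenceDB}}.
#' @param scheme a \code{\linkS4class{ScoringScheme}}.
#' @param thresholds named numeric vector with elements \code{family}
#'   and \code{subfamily} (percent identity, strict).
#' @param proteinId identifier recorded in the result.
#' @return a one-row data.frame: \code{protein_id}, \code{best_ref},
#'   \code{best_identity}, \code{level}, \code{family_label},
#'   \code{subfamily_label}.  Placeholder labels for FAMILY and
#'   NEW_FAMILY levels are \code{NA} until
#'   \code{\link{allocatePlaceholders}} fills them.
#' @examples
#' db <- makeReferenceDb(2, 2, seed = 7)$refdb
#' q <- as.character(refSequences(db)[[1]])
#' assignCyp(q, db)$level   # "SUBFAMILY" (identity 100)
#' @export
assignCyp <- function(query, refdb, scheme = ScoringScheme(),
                      thresholds = cypThresholds, proteinId = "query") {
  stopifnot(is(refdb, "ReferenceDB"))
  if (!length(refdb)) stop("empty reference database")
  ids <- sequenceIdentity(refdb, query, scheme)
  ## ties on identity break to the lexicographically smallest name
  best <- order(-ids, names(ids))[1]
  bestId <- unname(ids[best])
  level <- .levelFromIdentity(bestId, thresholds)
  ref <- refCypNames(refdb)[best]
  data.frame(
    protein_id = proteinId,
    best_ref = names(ids)[best],
    best_identity = bestId,
    level = level,
    family_label = if (level == "NEW_FAMILY") NA_character_
                   else familyLabel(ref),
    subfamily_label = if (level == "SUBFAMILY") subfamilyLabel(ref)
                      else NA_character_,
    stringsAsFactors = FALSE)
}

## connected components by single linkage over a boolean relation;
## component ids are renumbered by first appearance in input order.
.singleLinkage <- function(n, edges) {
  g <- igraph::make_graph(if (nrow(edges)) as.vector(t(edges))
                          else integer(0),
                          n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  match(memb, unique(memb))
}

.subLetters <- function(k) {
  ifelse(k <= 26L, LETTERS[k],
         paste0(LETTERS[(k - 1L) %/% 26L], LETTERS[(k - 1L) %% 26L + 1L]))
}

#' Allocate placeholder family and subfamily labels
#'
#' NEW_FAMILY queries receive placeholder families \code{NEWF001},
#' \code{NEWF002}, ... in order of first appearance, with queries
#' sharing more than the family threshold of mutual identity merged
#' into one placeholder family (single linkage); within a placeholder
#' family, the subfamily threshold partitions queries into lettered
#' placeholder subfamilies (\code{NEWF001A}, ...).  FAMILY-level
#' queries receive per-family new-subfamily placeholders
#' (\code{CYP105-newSF1}, ...), again merged by single linkage over
#' the subfamily threshold.
#'
#' @param assignments data.frame of raw assignments (one per query)
#'   with columns \code{species_id}, \code{protein_id}, \code{level},
#'   \code{family_label}, \code{subfamily_label}, sorted by
#'   (\code{species_id}, \code{protein_id}); unsorted input is an
#'   error, since the placeholder numbering depends on row order.
#' @param seqs an \code{AAStringSet} holding the query sequences,
#'   named by protein id.
#' @param scheme,thresholds see \code{\link{assignCyp}}.
#' @return \code{assignments} with all placeholder labels filled in.
#' @export
allocatePlaceholders <- function(assignments, seqs,
                                 scheme = ScoringScheme(),
                                 thresholds = cypThresholds) {
  if (nrow(assignments)) {
    ord <- order(assignments$species_id, assignments$protein_id)
    if (!identical(ord, seq_len(nrow(assignments))))
      stop("assignments must be sorted by (species_id, protein_id)")
  }
  pairIdentity <- function(idsA, idsB) {
    sequenceIdentity(AAStringSet(setNames(
      as.character(seqs[idsA]), idsA)), as.character(seqs[[idsB]]),
      scheme)
  }
  mutualIdentity <- function(ids) {
    n <- length(ids)
    m <- matrix(100, n, n)
    if (n > 1L)
      for (j in 2:n)
        m[1:(j - 1L), j] <- m[j, 1:(j - 1L)] <-
          pairIdentity(ids[1:(j - 1L)], ids[j])
    m
  }
  clusterOver <- function(ids, cut) {
    m <- mutualIdentity(ids)
    edges <- which(upper.tri(m) & m > cut, arr.ind = TRUE)
    .singleLinkage(length(ids), edges)
  }

  isNew <- which(assignments$level == "NEW_FAMILY")
  if (length(isNew)) {
    ids <- assignments$protein_id[isNew]
    fam <- clusterOver(ids, thresholds[["family"]])
    assignments$family_label[isNew] <- sprintf("NEWF%03d", fam)
    for (f in unique(fam)) {
      within <- which(fam == f)
      sub <- if (length(within) > 1L)
        clusterOver(ids[within], thresholds[["subfamily"]])
      else 1L
      assignments$subfamily_label[isNew[within]] <-
        paste0(sprintf("NEWF%03d", f), .subLetters(sub))
    }
  }

  isFam <- which(assignments$level == "FAMILY")
  for (famLab in unique(assignments$family_label[isFam])) {
    rows <- isFam[assignments$family_label[isFam] == famLab]
    sub <- if (length(rows) > 1L)
      clusterOver(assignments$protein_id[rows],
                  thresholds[["subfamily"]])
    else 1L
    assignments$subfamily_label[rows] <-
      paste0(famLab, "-newSF", sub)
  }
  assignments
}

#' Classify the complete P450s of one or more proteomes
#'
#' Runs \code{\link{assignCyp}} on every record, sorts by
#' (\code{species_id}, \code{protein_id}) and fills placeholder
#' labels with \code{\link{allocatePlaceholders}}.  Deterministic
#' given its inputs.
#'
#' @param aa an \code{AAStringSet} of COMPLETE-triaged records, named
#'   by protein id, with a \code{species_id} metadata column.
#' @param refdb a \code{\linkS4class{ReferenceDB}}.
#' @param scheme,thresholds see \code{\link{assignCyp}}.
#' @return a data.frame with one row per record: \code{species_id},
#'   \code{protein_id}, \code{best_ref}, \code{best_identity},
#'   \code{level}, \code{family_label}, \code{subfamily_label}.
#' @export
classifyProteome <- function(aa, refdb, scheme = ScoringScheme(),
                             thresholds = cypThresholds) {
  stopifnot(is(aa, "AAStringSet"))
  if (!length(aa)) {
    return(data.frame(species_id = character(0),
                      protein_id = character(0),
                      best_ref = character(0),
                      best_identity = numeric(0),
                      level = character(0),
                      family_label = character(0),
                      subfamily_label = character(0),
                      stringsAsFactors = FALSE))
  }
  sp <- mcols(aa)$species_id
  if (is.null(sp)) sp <- rep(NA_character_, length(aa))
  rows <- lapply(seq_along(aa), function(i)
    assignCyp(as.character(aa[[i]]), refdb, scheme, thresholds,
              proteinId = names(aa)[i]))
  out <- do.call(rbind, rows)
  out <- cbind(species_id = sp, out, stringsAsFactors = FALSE)
  ord <- order(out$species_id, out$protein_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  allocatePlaceholders(out, aa, scheme, thresholds)
}
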