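## Pairwise alignment and percent identity.
##
## Family/subfamily assignment is driven by percent identity under an
## optimal global (Needleman-Wunsch, affine-gap, end-gap penalised)
## alignment, with gap columns counted in the denominator.  This is a
## deterministic and stricter stand-in for the local BLAST identities
## used historically in P450 annotation; a local (Smith-Waterman)
## scheme is available for sensitivity analysis.  Alignments are
## computed by Biostrings::pairwiseAlignment, whose traceback is
## deterministic given the scoring scheme.

#' Align two amino-acid sequences
#'
#' @param a,b non-empty amino-acid sequences (character or
#'   \code{AAString}).
#' @param scheme a \code{\linkS4class{ScoringScheme}}; the default is
#'   BLOSUM62 with gap open 10 and gap extend 1, global.
#' @return a \code{PairwiseAlignments} object (see
#'   \code{\link{alignmentStats}} and \code{\link{percentIdentity}}).
#' @examples
#' aln <- alignPair("ACDE", "ACE")
#' alignmentStats(aln)    # 4 columns, 3 identical
#' percentIdentity(aln)   # 75
#' @export
alignPair <- function(a, b, scheme = ScoringScheme()) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(nzchar(a), nzchar(b))
  pairwiseAlignment(AAString(a), AAString(b),
                    type = scheme@type,
                    substitutionMatrix = substitutionMatrixOf(scheme),
                    gapOpening = scheme@gapOpen,
                    gapExtension = scheme@gapExt)
}

#' Column and identity counts of an alignment
#'
#' No alignment column is ever gap-versus-gap, so the column count is
#' the aligned length including gaps.
#'
#' @param aln a \code{PairwiseAlignments} object.
#' @return a data.frame with one row per alignment: \code{n_columns}
#'   and \code{n_identical}.
#' @export
alignmentStats <- function(aln) {
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  nId <- mapply(function(x, y) {
    cx <- strsplit(x, "")[[1]]
    cy <- strsplit(y, "")[[1]]
    sum(cx == cy & cx != "-")
  }, p, s, USE.NAMES = FALSE)
  data.frame(n_columns = nchar(p), n_identical = as.integer(nId))
}

#' Percent identity of an alignment
#'
#' 100 x identical columns / total columns; gap columns count in the
#' denominator.
#'
#' @param aln a \code{PairwiseAlignments} object.
#' @return numeric vector of identities in [0, 100].
#' @export
percentIdentity <- function(aln) {
  st <- alignmentStats(aln)
  if (any(st$n_columns == 0L))
    stop("alignment with zero columns")
  100 * st$n_identical / st$n_columns
}

#' Percent identity between a query and a set of references
#'
#' One optimal alignment per reference, all against the same query.
#'
#' @param refs an \code{AAStringSet} (or \code{\linkS4class{ReferenceDB}}).
#' @param query a single amino-acid sequence.
#' @param scheme a \code{\linkS4class{ScoringScheme}}.
#' @return named numeric vector of identities, one per reference.
#' @export
sequenceIdentity <- function(refs, query, scheme = ScoringScheme()) {
  if (is(refs, "ReferenceDB")) refs <- refSequences(refs)
  if (is.character(refs)) refs <- AAStringSet(refs)
  query <- as.character(query)
  stopifnot(nzchar(query), length(refs) > 0L)
  aln <- pairwiseAlignment(refs, AAString(query),
                           type = scheme@type,
                           substitutionMatrix =
                             substitutionMatrixOf(scheme),
                           gapOpening = scheme@gapOpen,
                           gapExtension = scheme@gapExt)
  setNames(percentIdentity(aln), names(refs))
}
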