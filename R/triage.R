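## Motif-based triage of P450 candidate hit proteins.
##
## Bacterial P450s carry two short conserved signatures: the K-helix
## EXXR salt-bridge motif and the CXG heme-loop motif around the
## axial cysteine.  A hit protein with both motifs is treated as a
## complete P450; with exactly one motif it is a pseudo-P450; with
## neither motif it is a fragment when short and a non-candidate
## otherwise.  Only complete P450s proceed to classification.

.triageLevels <- c("COMPLETE", "PSEUDO", "FRAGMENT", "NON_CANDIDATE")

#' Scan a sequence for the EXXR motif
#'
#' Reports every 0-based position \code{i} with \code{E} at \code{i}
#' and \code{R} at \code{i + 3}; the two middle residues may be
#' anything (including \code{X}).  Overlapping matches are all
#' reported, in ascending order.
#'
#' @param sequence an uppercase amino-acid string (or \code{AAString}).
#' @return integer vector of 0-based match positions.
#' @examples
#' scanExxr("AEAARAA")   # 1
#' scanExxr("EAAREAAR")  # 0 4
#' @export
scanExxr <- function(sequence) .scanMotif(sequence, "(?=E..R)")

#' Scan a sequence for the CXG motif
#'
#' Reports every 0-based position \code{i} with \code{C} at \code{i}
#' and \code{G} at \code{i + 2}.  Overlapping matches are all
#' reported.
#'
#' @inheritParams scanExxr
#' @return integer vector of 0-based match positions.
#' @examples
#' scanCxg("FGHGAHYCLG")  # 7
#' scanCxg("CAGCAG")      # 0 3
#' @export
scanCxg <- function(sequence) .scanMotif(sequence, "(?=C.G)")

.scanMotif <- function(sequence, lookahead) {
  s <- as.character(sequence)
  stopifnot(length(s) == 1L)
  if (!nzchar(s)) return(integer(0))
  hits <- gregexpr(lookahead, s, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
}

#' Triage one protein sequence
#'
#' @param sequence amino-acid string (or \code{AAString}).
#' @param fragmentMaxLen length below which a motif-less protein is
#'   called a fragment rather than a non-candidate (residues,
#'   default 300).
#' @return a list with \code{category} (one of \code{"COMPLETE"},
#'   \code{"PSEUDO"}, \code{"FRAGMENT"}, \code{"NON_CANDIDATE"}),
#'   \code{exxr_positions}, \code{cxg_positions} and \code{length}.
#' @export
triageSequence <- function(sequence, fragmentMaxLen = 300) {
  stopifnot(fragmentMaxLen > 0)
  s <- as.character(sequence)
  ex <- scanExxr(s)
  cx <- scanCxg(s)
  len <- nchar(s)
  category <- if (length(ex) && length(cx)) "COMPLETE"
    else if (length(ex) || length(cx)) "PSEUDO"
    else if (len < fragmentMaxLen) "FRAGMENT"
    else "NON_CANDIDATE"
  list(category = category, exxr_positions = ex, cxg_positions = cx,
       length = len)
}

#' Triage calls for a set of proteins
#'
#' @param aa an \code{AAStringSet} named by protein id.
#' @param fragmentMaxLen see \code{\link{triageSequence}}.
#' @return a \code{DataFrame} with one row per protein: columns
#'   \code{protein_id}, \code{category} (factor over the four triage
#'   levels), \code{n_exxr}, \code{n_cxg}, \code{length}, and
#'   \code{exxr_pos}/\code{cxg_pos} (\code{IntegerList} of 0-based
#'   motif positions).
#' @export
triageCalls <- function(aa, fragmentMaxLen = 300) {
  stopifnot(is(aa, "AAStringSet"))
  calls <- lapply(as.character(aa), triageSequence,
                  fragmentMaxLen = fragmentMaxLen)
  DataFrame(
    protein_id = if (length(aa)) names(aa) else character(0),
    category = factor(vapply(calls, `[[`, character(1), "category"),
                      levels = .triageLevels),
    n_exxr = vapply(calls, function(x) length(x$exxr_positions),
                    integer(1)),
    n_cxg = vapply(calls, function(x) length(x$cxg_positions),
                   integer(1)),
    length = vapply(calls, `[[`, integer(1), "length"),
    exxr_pos = IntegerList(lapply(calls, `[[`, "exxr_positions")),
    cxg_pos = IntegerList(lapply(calls, `[[`, "cxg_positions")))
}

#' Triage a whole proteome and tally the categories
#'
#' All records must belong to one species (records of several species
#' are triaged per species and tallied per species upstream).
#'
#' @param aa an \code{AAStringSet} named by protein id with a
#'   \code{species_id} metadata column (as produced by
#'   \code{\link{readProteomeFasta}}).
#' @param fragmentMaxLen see \code{\link{triageSequence}}.
#' @return a list with \code{calls} (see \code{\link{triageCalls}})
#'   and \code{summary}, a one-row data.frame of per-category counts
#'   that sum to the number of input proteins.
#' @export
triageProteome <- function(aa, fragmentMaxLen = 300) {
  stopifnot(is(aa, "AAStringSet"))
  sp <- unique(mcols(aa)$species_id)
  if (length(sp) > 1L)
    stop("triageProteome expects records of a single species, got: ",
         paste(sp, collapse = ", "))
  if (!length(sp)) sp <- NA_character_
  calls <- triageCalls(aa, fragmentMaxLen)
  counts <- table(calls$category)
  summary <- data.frame(
    species_id = sp,
    n_complete = as.integer(counts["COMPLETE"]),
    n_pseudo = as.integer(counts["PSEUDO"]),
    n_fragment = as.integer(counts["FRAGMENT"]),
    n_non_candidate = as.integer(counts["NON_CANDIDATE"]),
    n_total = length(aa))
  list(calls = calls, summary = summary)
}

#' Keep the complete P450s of a proteome
#'
#' Convenience subset used between triage and classification: only
#' proteins carrying both motifs flow on.
#'
#' @param aa an \code{AAStringSet}.
#' @param calls the matching \code{\link{triageCalls}} result
#'   (recomputed when omitted).
#' @param fragmentMaxLen see \code{\link{triageSequence}}.
#' @return the subset of \code{aa} with category \code{"COMPLETE"}.
#' @export
completeP450s <- function(aa, calls = NULL, fragmentMaxLen = 300) {
  if (is.null(calls)) calls <- triageCalls(aa, fragmentMaxLen)
  aa[calls$category == "COMPLETE"]
}
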