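## S4 classes shared across the package.

#' Parsed CYP names
#'
#' Vectorised representation of names issued under the standard CYP
#' nomenclature: the prefix \code{"CYP"}, an Arabic family number, an
#' optional subfamily of one or two capital letters, and an optional
#' member number (e.g. \code{CYP105D6}, \code{CYP107FH5},
#' \code{CYP154}).  Construct with \code{\link{parseCypName}}.
#'
#' @slot family integer vector of family numbers (positive).
#' @slot subfamily character vector of subfamily letters (\code{""}
#'   when absent; one or two capital letters otherwise).
#' @slot member integer vector of member numbers (\code{NA} when
#'   absent).
#'
#' @seealso \code{\link{parseCypName}}, \code{\link{familyLabel}},
#'   \code{\link{subfamilyLabel}}
#' @exportClass CypName
setClass("CypName",
  representation(family = "integer",
                 subfamily = "character",
                 member = "integer"))

setValidity("CypName", function(object) {
  n <- length(object@family)
  if (length(object@subfamily) != n || length(object@member) != n)
    return("family, subfamily and member slots must have equal length")
  if (any(is.na(object@family)) || any(object@family < 1L))
    return("family numbers must be positive integers")
  if (!all(grepl("^[A-Z]{0,2}$", object@subfamily)))
    return("subfamily must be zero to two capital letters")
  bad <- !is.na(object@member) & object@member < 1L
  if (any(bad))
    return("member numbers must be positive when present")
  if (any(!is.na(object@member) & object@subfamily == ""))
    return("a member number requires a subfamily letter")
  TRUE
})

#' @describeIn CypName number of names in the vector.
#' @param x a \code{CypName} object.
#' @export
setMethod("length", "CypName", function(x) length(x@family))

#' @describeIn CypName subset like an ordinary vector.
#' @param i index vector.
#' @export
setMethod("[", "CypName", function(x, i) {
  new("CypName", family = x@family[i], subfamily = x@subfamily[i],
      member = x@member[i])
})

#' @describeIn CypName format back to token strings
#'   (\code{parseCypName} composed with \code{as.character} is the
#'   identity on valid tokens).
#' @export
setMethod("as.character", "CypName", function(x) {
  if (!length(x)) return(character(0))   # paste0() would yield "CYP"
  paste0("CYP", x@family, x@subfamily,
         ifelse(is.na(x@member), "", x@member))
})

setMethod("show", "CypName", function(object) {
  cat("CypName vector of length", length(object), "\n")
  if (length(object))
    cat(" ", paste(head(as.character(object), 8), collapse = " "),
        if (length(object) > 8) "..." else "", "\n")
})

#' Alignment scoring scheme
#'
#' Substitution matrix plus affine gap penalties used for all pairwise
#' alignments.  The default (BLOSUM62, gap open 10, gap extend 1,
#' global) gives a deterministic, end-gap-penalised Needleman-Wunsch
#' alignment; a gap run of length L costs open + L * extend.  A local
#' (Smith-Waterman) variant is available for sensitivity analysis.
#'
#' @slot matrixName name of a substitution matrix shipped with
#'   \pkg{Biostrings} (e.g. \code{"BLOSUM62"}).
#' @slot gapOpen positive gap-opening penalty.
#' @slot gapExt positive gap-extension penalty.
#' @slot type \code{"global"} or \code{"local"}.
#'
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(matrixName = "character",
                 gapOpen = "numeric",
                 gapExt = "numeric",
                 type = "character"))

setValidity("ScoringScheme", function(object) {
  if (length(object@matrixName) != 1L) return("matrixName must be scalar")
  if (length(object@gapOpen) != 1L || object@gapOpen <= 0)
    return("gapOpen must be a single positive number")
  if (length(object@gapExt) != 1L || object@gapExt <= 0)
    return("gapExt must be a single positive number")
  if (!object@type %in% c("global", "local"))
    return("type must be 'global' or 'local'")
  m <- substitutionMatrixOf(object)
  if (!isTRUE(all.equal(m, t(m))))
    return("substitution matrix must be symmetric")
  TRUE
})

#' @param matrixName,gapOpen,gapExt,type see slot documentation.
#' @return \code{ScoringScheme()} returns a validated scheme object.
#' @rdname ScoringScheme-class
#' @examples
#' ScoringScheme()                      # BLOSUM62, 10/1, global
#' ScoringScheme(type = "local")       # Smith-Waterman identity
#' @export
ScoringScheme <- function(matrixName = "BLOSUM62", gapOpen = 10,
                          gapExt = 1, type = c("global", "local")) {
  type <- match.arg(type)
  new("ScoringScheme", matrixName = matrixName, gapOpen = gapOpen,
      gapExt = gapExt, type = type)
}

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme:", object@matrixName,
      sprintf("(gap open %g, extend %g, %s alignment)\n",
              object@gapOpen, object@gapExt, object@type))
})

## cache of substitution matrices loaded from Biostrings
.matrixCache <- new.env(parent = emptyenv())

#' Look up the substitution matrix of a scoring scheme
#'
#' @param scheme a \code{\linkS4class{ScoringScheme}}.
#' @return the named substitution matrix.
#' @export
substitutionMatrixOf <- function(scheme) {
  nm <- scheme@matrixName
  if (!exists(nm, envir = .matrixCache)) {
    e <- new.env()
    ok <- tryCatch({
      utils::data(list = nm, package = "Biostrings", envir = e)
      TRUE
    }, warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || !exists(nm, envir = e))
      stop("unknown substitution matrix: ", nm)
    assign(nm, get(nm, envir = e), envir = .matrixCache)
  }
  get(nm, envir = .matrixCache)
}

#' Reference database of named P450 proteins
#'
#' Holds the named reference sequences that queries are compared
#' against.  Every entry carries a valid CYP name (unique across the
#' database) and every sequence must triage as a complete P450, i.e.
#' carry both the EXXR and the CXG motif.
#'
#' @slot sequences an \code{AAStringSet}; names are the CYP name
#'   strings.
#' @slot cypNames the parsed \code{\linkS4class{CypName}} vector,
#'   parallel to \code{sequences}.
#'
#' @seealso \code{\link{readReferenceFasta}},
#'   \code{\link{makeReferenceDb}}
#' @exportClass ReferenceDB
setClass("ReferenceDB",
  representation(sequences = "AAStringSet", cypNames = "CypName"))

setValidity("ReferenceDB", function(object) {
  n <- length(object@sequences)
  if (length(object@cypNames) != n)
    return("sequences and cypNames must have equal length")
  nms <- as.character(object@cypNames)
  if (anyDuplicated(nms))
    return(paste("duplicated reference name:", nms[duplicated(nms)][1]))
  if (!identical(as.character(names(object@sequences)), nms))
    return("sequence names must equal the formatted CYP names")
  if (n) {
    seqs <- as.character(object@sequences)
    hasE <- vapply(seqs, function(s) length(scanExxr(s)) > 0, logical(1))
    hasC <- vapply(seqs, function(s) length(scanCxg(s)) > 0, logical(1))
    if (!all(hasE & hasC))
      return(paste("reference is not a complete P450 (missing motif):",
                   nms[!(hasE & hasC)][1]))
  }
  TRUE
})

#' @param sequences an \code{AAStringSet} (or named character vector)
#'   of reference sequences whose names are CYP name tokens.
#' @return \code{ReferenceDB()} returns a validated database.
#' @rdname ReferenceDB-class
#' @export
ReferenceDB <- function(sequences) {
  if (is.character(sequences)) sequences <- AAStringSet(sequences)
  if (is.null(names(sequences)))
    stop("reference sequences must be named with CYP name tokens")
  cyp <- parseCypName(names(sequences))
  names(sequences) <- as.character(cyp)
  mcols(sequences) <- NULL
  new("ReferenceDB", sequences = sequences, cypNames = cyp)
}

#' @describeIn ReferenceDB number of reference sequences.
#' @param x a \code{ReferenceDB}.
#' @export
setMethod("length", "ReferenceDB", function(x) length(x@sequences))

#' @describeIn ReferenceDB the reference name strings.
#' @export
setMethod("names", "ReferenceDB", function(x) names(x@sequences))

#' @describeIn ReferenceDB subset by index or name.
#' @param i index vector.
#' @export
setMethod("[", "ReferenceDB", function(x, i) {
  if (is.character(i)) i <- match(i, names(x))
  new("ReferenceDB", sequences = x@sequences[i],
      cypNames = x@cypNames[i])
})

setMethod("show", "ReferenceDB", function(object) {
  cat("ReferenceDB with", length(object), "named P450 sequences\n")
  fams <- unique(familyLabel(object@cypNames))
  cat(" ", length(fams), "families:",
      paste(head(fams, 6), collapse = " "),
      if (length(fams) > 6) "..." else "", "\n")
})

#' Sequences of a reference database
#' @param db a \code{\linkS4class{ReferenceDB}}.
#' @return an \code{AAStringSet}.
#' @export
refSequences <- function(db) db@sequences

#' Parsed names of a reference database
#' @param db a \code{\linkS4class{ReferenceDB}}.
#' @return a \code{\linkS4class{CypName}} vector.
#' @export
refCypNames <- function(db) db@cypNames
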