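#' Parse CYP name tokens
#'
#' Splits tokens of the standard nomenclature form
#' \code{CYP<family><subfamily letters><member>} greedily: the digits
#' following the (case-insensitive) \code{CYP} prefix are the family
#' number, up to two following capital letters are the subfamily, and
#' trailing digits are the member number.  Family-only
#' (\code{"CYP154"}) and family+subfamily (\code{"CYP107W"}) tokens
#' are valid.
#'
#' @param tokens character vector of name tokens.
#' @return a \code{\linkS4class{CypName}} vector, parallel to
#'   \code{tokens}.
#' @examples
#' x <- parseCypName(c("CYP105D6", "CYP107FH5", "CYP154"))
#' familyLabel(x)      # "CYP105" "CYP107" "CYP154"
#' subfamilyLabel(x)   # "CYP105D" "CYP107FH" NA
#' as.character(x)     # round-trips the tokens
#' @export
parseCypName <- function(tokens) {
  stopifnot(is.character(tokens))
  bad <- !grepl("^[Cc][Yy][Pp]", tokens)
  if (any(bad))
    stop("not a CYP name token (missing 'CYP' prefix): ",
         tokens[bad][1])
  body <- sub("^[Cc][Yy][Pp]", "", tokens)
  nodigit <- !grepl("^[0-9]", body)
  if (any(nodigit))
    stop("no family number after 'CYP' in token: ", tokens[nodigit][1])
  toolong <- grepl("^[0-9]+[A-Z]{3,}", body)
  if (any(toolong))
    stop("more than two subfamily letters in token: ",
         tokens[toolong][1])
  m <- regmatches(body, regexec("^([0-9]+)([A-Z]{0,2})([0-9]*)$", body))
  unparsed <- lengths(m) == 0L
  if (any(unparsed))
    stop("trailing characters in CYP name token: ", tokens[unparsed][1])
  fam <- vapply(m, function(p) as.integer(p[2]), integer(1))
  sub <- vapply(m, function(p) p[3], character(1))
  mem <- vapply(m, function(p)
    if (p[4] == "") NA_integer_ else as.integer(p[4]), integer(1))
  new("CypName", family = fam, subfamily = sub, member = mem)
}

#' Family and subfamily labels of parsed CYP names
#'
#' \code{familyLabel} gives \code{"CYP"} + family number;
#' \code{subfamilyLabel} appends the subfamily letters, or is
#' \code{NA} where the token carried no subfamily.
#'
#' @param x a \code{\linkS4class{CypName}} vector.
#' @return a character vector parallel to \code{x}.
#' @export
familyLabel <- function(x) {
  stopifnot(is(x, "CypName"))
  paste0("CYP", x@family)
}

#' @rdname familyLabel
#' @export
subfamilyLabel <- function(x) {
  stopifnot(is(x, "CypName"))
  ifelse(x@subfamily == "", NA_character_,
         paste0("CYP", x@family, x@subfamily))
}
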