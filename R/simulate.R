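## Synthetic cohorts with known truth.
##
## The generator emulates what the pipeline consumes in the field:
## per-species proteomes whose hit proteins carry planted motif
## structure, a reference database of named P450s with controlled
## pairwise identities, and BGC layouts with known P450 membership.
## Identity targeting works by iterative random substitution with
## re-verification against the package's own aligner (accept/reject),
## because gapped global identity is not a simple function of the
## substitution count.  Synthetic CYP family numbers start at 9001 so
## they can never collide with real committee-issued names.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Random amino-acid sequence
#'
#' Uniform over the 20 standard residues; uses the caller's RNG
#' stream.
#'
#' @param n length in residues.
#' @return a character scalar.
#' @export
randomAASequence <- function(n) {
  paste(sample(.AA20, n, replace = TRUE), collapse = "")
}

## remove every occurrence of a motif by overwriting its first anchor
.stripMotif <- function(chars, scanner, offset1 = 1L) {
  repeat {
    pos <- scanner(paste(chars, collapse = ""))
    if (!length(pos)) return(chars)
    chars[pos + offset1] <- "L"
  }
}

.plantExxr <- function(chars, at) {
  chars[at] <- "E"; chars[at + 3L] <- "R"; chars
}

.plantCxg <- function(chars, at) {
  chars[at] <- "C"; chars[at + 2L] <- "G"; chars
}

.exxrAnchor <- function(len) max(4L, floor(0.70 * len))
.cxgAnchor <- function(len) min(len - 2L, floor(0.90 * len))

#' Random complete-P450-like sequence
#'
#' A random sequence with an EXXR motif planted around 70% of the
#' length (K-helix territory) and a CXG motif around 90% (heme
#' loop), so it triages COMPLETE.
#'
#' @param len length in residues (at least 20).
#' @return a character scalar.
#' @export
makeP450Seed <- function(len = 400) {
  stopifnot(len >= 20)
  chars <- sample(.AA20, len, replace = TRUE)
  chars <- .plantExxr(chars, .exxrAnchor(len))
  chars <- .plantCxg(chars, .cxgAnchor(len))
  paste(chars, collapse = "")
}

## the anchor residues of the first occurrence of each motif
## (1-based), protected from mutation so the motifs survive
.motifAnchors <- function(sequence) {
  e <- scanExxr(sequence)
  cx <- scanCxg(sequence)
  c(if (length(e)) c(e[1] + 1L, e[1] + 4L),
    if (length(cx)) c(cx[1] + 1L, cx[1] + 3L))
}

#' Mutate a sequence to a target global identity
#'
#' Substitutes random positions (never the protected motif anchors)
#' until the global-alignment identity to the seed sequence, measured
#' with the package's own aligner, lies within +/-2 points of the
#' target.  The number of substitutions is adjusted between attempts
#' from the measured error.
#'
#' @param seedSequence sequence of at least 100 residues.
#' @param targetIdentity desired percent identity in [10, 100].
#' @param scheme a \code{\linkS4class{ScoringScheme}}.
#' @param seed optional RNG seed; when \code{NULL} the caller's RNG
#'   stream is used.
#' @param maxAttempts attempts before giving up with an error.
#' @return a sequence whose identity to \code{seedSequence} is within
#'   +/-2 points of \code{targetIdentity}; motifs present in the seed
#'   survive.
#' @export
mutateToIdentity <- function(seedSequence, targetIdentity,
                             scheme = ScoringScheme(), seed = NULL,
                             maxAttempts = 40L) {
  stopifnot(nchar(seedSequence) >= 100,
            targetIdentity >= 10, targetIdentity <= 100)
  run <- function() {
    if (targetIdentity == 100) return(seedSequence)
    chars0 <- strsplit(seedSequence, "")[[1]]
    len <- length(chars0)
    protect <- .motifAnchors(seedSequence)
    free <- setdiff(seq_len(len), protect)
    m <- round(len * (1 - targetIdentity / 100))
    for (attempt in seq_len(maxAttempts)) {
      m <- min(max(m, 0L), length(free))
      chars <- chars0
      if (m > 0L) {
        pos <- sample(free, m)
        for (p in pos)
          chars[p] <- sample(setdiff(.AA20, chars0[p]), 1)
      }
      cand <- paste(chars, collapse = "")
      id <- unname(sequenceIdentity(AAStringSet(c(x = cand)),
                                    seedSequence, scheme))
      if (abs(id - targetIdentity) <= 2) return(cand)
      m <- m + round((id - targetIdentity) * len / 100)
    }
    stop("could not reach identity ", targetIdentity,
         " within +/-2 points in ", maxAttempts, " attempts")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a reference database with certified identities
#'
#' One seed sequence per family (family numbers 9001, 9002, ...);
#' subfamily representative A is the seed itself, further
#' representatives (B, C, ...) are mutated to about 50% identity to
#' the seed, i.e. within the 45-54% window that separates family
#' membership from subfamily membership.  Cross-family reference
#' pairs are verified below 35% identity and regenerated on failure.
#' All references triage COMPLETE by construction.
#'
#' @param nFamilies number of families (at least 1).
#' @param subfamiliesPerFamily representatives per family (1-26).
#' @param seed RNG seed; \code{NULL} uses the caller's stream.
#' @param seqLength reference length in residues.
#' @param scheme a \code{\linkS4class{ScoringScheme}}.
#' @param maxAttempts regeneration attempts per sequence.
#' @return a list with \code{refdb}
#'   (a \code{\linkS4class{ReferenceDB}}) and \code{certificate}, a
#'   data.frame of all pairwise reference identities recomputed with
#'   the aligner (\code{ref1}, \code{ref2}, \code{same_family},
#'   \code{identity}).
#' @export
makeReferenceDb <- function(nFamilies, subfamiliesPerFamily = 1L,
                            seed = NULL, seqLength = 400,
                            scheme = ScoringScheme(),
                            maxAttempts = 20L) {
  stopifnot(nFamilies >= 1, subfamiliesPerFamily >= 1,
            subfamiliesPerFamily <= 26)
  run <- function() {
    seqs <- character(0)
    famOf <- integer(0)
    accept <- function(cand, fam) {
      other <- seqs[famOf != fam]
      !length(other) ||
        all(sequenceIdentity(AAStringSet(other), cand, scheme) < 35)
    }
    for (f in seq_len(nFamilies)) {
      famNum <- 9000L + f
      for (r in seq_len(subfamiliesPerFamily)) {
        nm <- paste0("CYP", famNum, LETTERS[r], 1L)
        for (attempt in seq_len(maxAttempts)) {
          cand <- if (r == 1L) makeP450Seed(seqLength)
            else mutateToIdentity(seqs[paste0("CYP", famNum, "A1")],
                                  50, scheme)
          if (accept(cand, f)) break
          if (attempt == maxAttempts)
            stop("could not satisfy the <35% cross-family identity ",
                 "constraint for ", nm)
        }
        seqs[nm] <- cand
        famOf <- c(famOf, f)
      }
    }
    refdb <- ReferenceDB(AAStringSet(seqs))
    nms <- names(refdb)
    cert <- do.call(rbind, lapply(seq_along(nms)[-1], function(j) {
      ids <- sequenceIdentity(refSequences(refdb)[seq_len(j - 1L)],
                              as.character(refSequences(refdb)[[j]]),
                              scheme)
      data.frame(ref1 = nms[seq_len(j - 1L)], ref2 = nms[j],
                 same_family = famOf[seq_len(j - 1L)] == famOf[j],
                 identity = unname(ids), stringsAsFactors = FALSE)
    }))
    if (is.null(cert))
      cert <- data.frame(ref1 = character(0), ref2 = character(0),
                         same_family = logical(0),
                         identity = numeric(0))
    list(refdb = refdb, certificate = cert)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Synthetic-cohort specification
#'
#' Bundles every knob of the generator.  Identity targets must stay
#' outside the bands [37, 43] and [52, 58] around the 40%/55%
#' nomenclature thresholds so that planted labels are recovered
#' deterministically; set \code{stressThresholds = TRUE} to lift the
#' restriction when deliberately generating boundary cases.
#'
#' @slot seed integer RNG seed; the whole bundle is a deterministic
#'   function of the spec.
#' @slot nSpecies number of species.
#' @slot nComplete,nPseudo,nFragment,nNonCandidate per-species counts
#'   of complete P450s, single-motif pseudo-P450s, short motif-less
#'   fragments and long motif-less non-candidates.
#' @slot nFamilies,subfamiliesPerFamily reference database layout.
#' @slot clustersPerSpecies BGC intervals per species (must be able
#'   to host the in-cluster P450s).
#' @slot fracInClusters fraction of complete P450 genes placed inside
#'   clusters.
#' @slot typePalette cluster type labels to draw from.
#' @slot levelMix named proportions of SUBFAMILY / FAMILY /
#'   NEW_FAMILY planted assignment levels.
#' @slot subfamilyIdentityTargets,familyIdentityTargets percent
#'   identity targets cycled over the planted proteins.
#' @slot newFamilyMaxIdentity ceiling verified for new-family queries
#'   against every reference and against each other.
#' @slot seqLength,fragmentMaxLen residue lengths.
#' @slot stressThresholds allow in-band identity targets.
#' @exportClass SimSpec
setClass("SimSpec",
  representation(seed = "numeric", nSpecies = "integer",
                 nComplete = "integer", nPseudo = "integer",
                 nFragment = "integer", nNonCandidate = "integer",
                 nFamilies = "integer",
                 subfamiliesPerFamily = "integer",
                 clustersPerSpecies = "integer",
                 fracInClusters = "numeric",
                 typePalette = "character", levelMix = "numeric",
                 subfamilyIdentityTargets = "numeric",
                 familyIdentityTargets = "numeric",
                 newFamilyMaxIdentity = "numeric",
                 seqLength = "numeric", fragmentMaxLen = "numeric",
                 stressThresholds = "logical"))

setValidity("SimSpec", function(object) {
  inBand <- function(x) (x >= 37 & x <= 43) | (x >= 52 & x <= 58)
  if (!object@stressThresholds) {
    if (any(inBand(object@subfamilyIdentityTargets)) ||
        any(inBand(object@familyIdentityTargets)))
      return(paste("identity targets must avoid the bands [37,43]",
                   "and [52,58] unless stressThresholds is set"))
  }
  if (any(object@subfamilyIdentityTargets <= 55))
    return("subfamily identity targets must exceed 55")
  if (any(object@familyIdentityTargets <= 40 |
          object@familyIdentityTargets > 55))
    return("family identity targets must lie in (40, 55]")
  if (object@fracInClusters < 0 || object@fracInClusters > 1)
    return("fracInClusters must lie in [0, 1]")
  if (abs(sum(object@levelMix) - 1) > 1e-8 || any(object@levelMix < 0))
    return("levelMix must be non-negative and sum to 1")
  if (!all(c("SUBFAMILY", "FAMILY", "NEW_FAMILY") %in%
           names(object@levelMix)))
    return("levelMix needs SUBFAMILY, FAMILY and NEW_FAMILY entries")
  if (round(object@fracInClusters * object@nComplete) >
      object@clustersPerSpecies)
    return("clustersPerSpecies too small for fracInClusters")
  if (!length(object@typePalette))
    return("typePalette must be non-empty")
  TRUE
})

#' @param seed,nSpecies,nComplete,nPseudo,nFragment,nNonCandidate,nFamilies,subfamiliesPerFamily,clustersPerSpecies,fracInClusters,typePalette,levelMix,subfamilyIdentityTargets,familyIdentityTargets,newFamilyMaxIdentity,seqLength,fragmentMaxLen,stressThresholds
#'   see the slot documentation.
#' @return \code{simSpec()} returns a validated \code{SimSpec}.
#' @rdname SimSpec-class
#' @export
simSpec <- function(seed = 1L, nSpecies = 5L, nComplete = 12L,
                    nPseudo = 1L, nFragment = 2L, nNonCandidate = 1L,
                    nFamilies = 3L, subfamiliesPerFamily = 2L,
                    clustersPerSpecies = 6L, fracInClusters = 0.2,
                    typePalette = c("terpene", "T1PKS", "NRPS",
                                    "T3PKS", "bacteriocin"),
                    levelMix = c(SUBFAMILY = 0.6, FAMILY = 0.25,
                                 NEW_FAMILY = 0.15),
                    subfamilyIdentityTargets = c(62, 75, 88),
                    familyIdentityTargets = c(45, 48, 50),
                    newFamilyMaxIdentity = 37,
                    seqLength = 400, fragmentMaxLen = 300,
                    stressThresholds = FALSE) {
  new("SimSpec", seed = seed, nSpecies = as.integer(nSpecies),
      nComplete = as.integer(nComplete), nPseudo = as.integer(nPseudo),
      nFragment = as.integer(nFragment),
      nNonCandidate = as.integer(nNonCandidate),
      nFamilies = as.integer(nFamilies),
      subfamiliesPerFamily = as.integer(subfamiliesPerFamily),
      clustersPerSpecies = as.integer(clustersPerSpecies),
      fracInClusters = fracInClusters, typePalette = typePalette,
      levelMix = levelMix,
      subfamilyIdentityTargets = subfamilyIdentityTargets,
      familyIdentityTargets = familyIdentityTargets,
      newFamilyMaxIdentity = newFamilyMaxIdentity,
      seqLength = seqLength, fragmentMaxLen = fragmentMaxLen,
      stressThresholds = stressThresholds)
}

setMethod("show", "SimSpec", function(object) {
  cat(sprintf(paste0("SimSpec: %d species x %d complete P450s ",
                     "(+%d pseudo, %d fragment, %d non-candidate), ",
                     "%d families x %d subfamilies, %d clusters/",
                     "species, seed %g\n"),
              object@nSpecies, object@nComplete, object@nPseudo,
              object@nFragment, object@nNonCandidate,
              object@nFamilies, object@subfamiliesPerFamily,
              object@clustersPerSpecies, object@seed))
})

## fresh registry for cohort-level identity verification
.newRegistry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$newSeqs <- character(0)
  reg$famSeqs <- list()
  reg
}

## a new-family query: random, motif-complete, and verified below the
## ceiling against every reference and every previously accepted
## new-family query
.makeNewFamilyQuery <- function(refdb, registry, ceiling, seqLength,
                                scheme, maxAttempts = 20L) {
  for (attempt in seq_len(maxAttempts)) {
    cand <- makeP450Seed(seqLength)
    idsRef <- sequenceIdentity(refdb, cand, scheme)
    ok <- all(idsRef < ceiling)
    if (ok && length(registry$newSeqs))
      ok <- all(sequenceIdentity(AAStringSet(registry$newSeqs), cand,
                                 scheme) < ceiling)
    if (ok) {
      registry$newSeqs <- c(registry$newSeqs, cand)
      return(cand)
    }
  }
  stop("could not generate a new-family query below ", ceiling,
       "% identity")
}

## a planted query derived from one reference; verified so that the
## planted reference is the strict best hit and references of OTHER
## families sit below the new-family ceiling (same-family references
## legitimately share intermediate identity with the query)
.makePlantedQuery <- function(refName, target, refdb, registry,
                              ceiling, scheme, maxAttempts = 10L) {
  refSeq <- as.character(refSequences(refdb)[[refName]])
  allFams <- familyLabel(refCypNames(refdb))
  famLab <- allFams[match(refName, names(refdb))]
  for (attempt in seq_len(maxAttempts)) {
    cand <- mutateToIdentity(refSeq, target, scheme)
    ids <- sequenceIdentity(refdb, cand, scheme)
    others <- ids[names(ids) != refName]
    crossFam <- others[allFams[match(names(others),
                                     names(refdb))] != famLab]
    ok <- (!length(others) || ids[[refName]] > max(others)) &&
      all(crossFam < ceiling)
    if (ok && target <= 55) {
      ## family-level query: keep mutual identities among family-level
      ## queries of the same family below the subfamily band so each
      ## founds its own placeholder subfamily
      prev <- registry$famSeqs[[famLab]]
      if (length(prev))
        ok <- all(sequenceIdentity(AAStringSet(prev), cand,
                                   scheme) < 52)
    }
    if (ok) {
      if (target <= 55)
        registry$famSeqs[[famLab]] <- c(registry$famSeqs[[famLab]],
                                        cand)
      return(cand)
    }
  }
  stop("could not plant a query at identity ", target, " to ",
       refName)
}

#' Generate one synthetic species proteome with truth
#'
#' Complete proteins are derived from planted references at planted
#' identities (or are random new-family queries), pseudo proteins
#' carry exactly one motif, fragments are short and motif-less,
#' non-candidates long and motif-less.  Genes are laid out
#' non-overlapping on one synthetic contig with
#' \code{gene_id == protein_id}.
#'
#' @param speciesId species identifier.
#' @param complete data.frame with one row per complete protein:
#'   \code{ref} (reference name, \code{NA} for a new-family query)
#'   and \code{identity} (target percent, \code{NA} for new-family).
#' @param refdb a \code{\linkS4class{ReferenceDB}}.
#' @param nPseudo,nFragment,nNonCandidate counts of the other
#'   categories.
#' @param scheme a \code{\linkS4class{ScoringScheme}}.
#' @param seqLength,fragmentMaxLen residue lengths.
#' @param newFamilyMaxIdentity verification ceiling for new-family
#'   and cross-reference identities.
#' @param seed optional RNG seed (\code{NULL}: caller's stream).
#' @param registry internal cohort-level registry; leave default.
#' @return a list with \code{proteins} (an \code{AAStringSet} with
#'   \code{species_id} metadata), \code{genes} (a \code{GRanges})
#'   and \code{truth} (a data.frame with the planted category,
#'   level, family and subfamily of every protein).
#' @export
makeProteome <- function(speciesId, complete, refdb, nPseudo = 0L,
                         nFragment = 0L, nNonCandidate = 0L,
                         scheme = ScoringScheme(), seqLength = 400,
                         fragmentMaxLen = 300,
                         newFamilyMaxIdentity = 37, seed = NULL,
                         registry = .newRegistry()) {
  run <- function() {
    seqs <- character(0)
    truth <- list()
    addTruth <- function(id, category, level = NA_character_,
                         ref = NA_character_, target = NA_real_,
                         fam = NA_character_, sub = NA_character_) {
      truth[[length(truth) + 1L]] <<- data.frame(
        species_id = speciesId, protein_id = id, category = category,
        level = level, ref_name = ref, target_identity = target,
        family_label = fam, subfamily_label = sub, in_bgc = FALSE,
        stringsAsFactors = FALSE)
    }
    nextId <- function() sprintf("%s_p%03d", speciesId,
                                 length(seqs) + 1L)
    for (i in seq_len(nrow(complete))) {
      id <- nextId()
      refName <- complete$ref[i]
      target <- complete$identity[i]
      if (is.na(refName)) {
        seqs[id] <- .makeNewFamilyQuery(refdb, registry,
                                        newFamilyMaxIdentity,
                                        seqLength, scheme)
        addTruth(id, "COMPLETE", level = "NEW_FAMILY")
      } else {
        seqs[id] <- .makePlantedQuery(refName, target, refdb,
                                      registry, newFamilyMaxIdentity,
                                      scheme)
        cyp <- refCypNames(refdb)[match(refName, names(refdb))]
        level <- if (target > 55) "SUBFAMILY" else "FAMILY"
        addTruth(id, "COMPLETE", level = level, ref = refName,
                 target = target, fam = familyLabel(cyp),
                 sub = if (level == "SUBFAMILY") subfamilyLabel(cyp)
                       else NA_character_)
      }
    }
    for (i in seq_len(nPseudo)) {
      id <- nextId()
      chars <- sample(.AA20, seqLength, replace = TRUE)
      if (i %% 2L == 1L) {      # EXXR-only
        chars <- .stripMotif(chars, scanCxg)
        chars <- .plantExxr(chars, .exxrAnchor(seqLength))
      } else {                  # CXG-only
        chars <- .stripMotif(chars, scanExxr)
        chars <- .plantCxg(chars, .cxgAnchor(seqLength))
      }
      seqs[id] <- paste(chars, collapse = "")
      addTruth(id, "PSEUDO")
    }
    fragLen <- max(50L, round(0.4 * fragmentMaxLen))
    for (i in seq_len(nFragment)) {
      id <- nextId()
      chars <- sample(.AA20, fragLen, replace = TRUE)
      chars <- .stripMotif(.stripMotif(chars, scanExxr), scanCxg)
      seqs[id] <- paste(chars, collapse = "")
      addTruth(id, "FRAGMENT")
    }
    for (i in seq_len(nNonCandidate)) {
      id <- nextId()
      chars <- sample(.AA20, seqLength + 50L, replace = TRUE)
      chars <- .stripMotif(.stripMotif(chars, scanExxr), scanCxg)
      seqs[id] <- paste(chars, collapse = "")
      addTruth(id, "NON_CANDIDATE")
    }
    aa <- AAStringSet(seqs)
    mcols(aa)$species_id <- rep(speciesId, length(aa))
    n <- length(seqs)
    genes <- GRanges(rep("ctg1", n),
                     IRanges(start = (seq_len(n) - 1L) * 1500L + 1L,
                             width = 1200L),
                     strand = rep("+", n))
    mcols(genes)$gene_id <- names(seqs)
    mcols(genes)$species_id <- rep(speciesId, n)
    truth <- if (length(truth)) do.call(rbind, truth)
      else data.frame(species_id = character(0),
                      protein_id = character(0),
                      category = character(0), level = character(0),
                      ref_name = character(0),
                      target_identity = numeric(0),
                      family_label = character(0),
                      subfamily_label = character(0),
                      in_bgc = logical(0), stringsAsFactors = FALSE)
    list(proteins = aa, genes = genes, truth = truth)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a full synthetic cohort with truth
#'
#' Builds the reference database, one proteome per species, and a BGC
#' layout in which a planted fraction of the complete P450 genes sit
#' inside clusters (one cluster per in-BGC gene, plus empty
#' clusters).  The whole bundle is a deterministic function of the
#' spec, and running the pipeline over it reproduces the returned
#' truth summary exactly.
#'
#' @param spec a \code{\linkS4class{SimSpec}}.
#' @param scheme a \code{\linkS4class{ScoringScheme}}.
#' @return a list with elements \code{spec}, \code{refdb},
#'   \code{certificate}, \code{species} (per species: proteins,
#'   genes, truth), \code{clusters} (a \code{GRanges} over all
#'   species), \code{truth} (combined truth table) and
#'   \code{truthSummary} (the expected \code{\link{cohortSummary}}
#'   row).
#' @examples
#' \donttest{
#' cohort <- makeCohort(simSpec(seed = 42, nSpecies = 2,
#'                              nComplete = 4))
#' res <- runCohortPipeline(cohort)
#' res$summary$total_p450s   # 8, as planted
#' }
#' @export
makeCohort <- function(spec, scheme = ScoringScheme()) {
  stopifnot(is(spec, "SimSpec"))
  with_seed(spec@seed, {
    ref <- makeReferenceDb(spec@nFamilies, spec@subfamiliesPerFamily,
                           seed = NULL, seqLength = spec@seqLength,
                           scheme = scheme)
    refdb <- ref$refdb
    nRefs <- length(refdb)
    registry <- .newRegistry()
    n <- spec@nComplete
    nNew <- floor(spec@levelMix[["NEW_FAMILY"]] * n)
    nFam <- floor(spec@levelMix[["FAMILY"]] * n)
    nSub <- n - nNew - nFam
    species <- list()
    clusterRows <- list()
    counter <- 0L
    for (s in seq_len(spec@nSpecies)) {
      sp <- sprintf("sp%02d", s)
      pick <- function(pool, i) pool[(i - 1L) %% length(pool) + 1L]
      rows <- lapply(seq_len(n), function(i) {
        counter <<- counter + 1L
        if (i <= nSub)
          data.frame(ref = pick(names(refdb), counter),
                     identity = pick(spec@subfamilyIdentityTargets,
                                     counter),
                     stringsAsFactors = FALSE)
        else if (i <= nSub + nFam)
          data.frame(ref = pick(names(refdb), counter),
                     identity = pick(spec@familyIdentityTargets,
                                     counter),
                     stringsAsFactors = FALSE)
        else
          data.frame(ref = NA_character_, identity = NA_real_,
                     stringsAsFactors = FALSE)
      })
      complete <- do.call(rbind, rows)
      if (is.null(complete))
        complete <- data.frame(ref = character(0),
                               identity = numeric(0))
      prot <- makeProteome(sp, complete, refdb,
                           nPseudo = spec@nPseudo,
                           nFragment = spec@nFragment,
                           nNonCandidate = spec@nNonCandidate,
                           scheme = scheme,
                           seqLength = spec@seqLength,
                           fragmentMaxLen = spec@fragmentMaxLen,
                           newFamilyMaxIdentity =
                             spec@newFamilyMaxIdentity,
                           registry = registry)
      ## BGC layout: one cluster around each chosen complete gene,
      ## then empty clusters downstream of the gene array
      k <- round(spec@fracInClusters * n)
      chosen <- if (k > 0L) sort(sample(seq_len(n), k)) else integer(0)
      prot$truth$in_bgc[chosen] <- TRUE
      g <- prot$genes
      lastEnd <- if (length(g)) max(end(g)) else 0L
      for (j in seq_len(spec@clustersPerSpecies)) {
        if (j <= k) {
          cs <- start(g)[chosen[j]] - 100L
          ce <- end(g)[chosen[j]] + 100L
        } else {
          cs <- lastEnd + 5000L + (j - k - 1L) * 4000L
          ce <- cs + 2500L
        }
        nLab <- if (stats::runif(1) < 0.2) 2L else 1L
        labs <- sample(spec@typePalette, min(nLab,
                                             length(spec@typePalette)))
        known <- if (stats::runif(1) < 0.3)
          sample(c("filipin", "oligomycin A", "nystatin",
                   "erythromycin"), 1) else NA_character_
        clusterRows[[length(clusterRows) + 1L]] <- list(
          species_id = sp, cluster_id = sprintf("%s_c%02d", sp, j),
          contig = "ctg1", start = max(1L, cs), end = ce,
          types = labs, known = known,
          sim = if (is.na(known)) NA_real_
                else round(stats::runif(1, 60, 95), 1))
      }
      species[[sp]] <- prot
    }
    clusters <- GRanges(
      vapply(clusterRows, `[[`, character(1), "contig"),
      IRanges(vapply(clusterRows, `[[`, numeric(1), "start"),
              vapply(clusterRows, `[[`, numeric(1), "end")))
    mcols(clusters)$species_id <-
      vapply(clusterRows, `[[`, character(1), "species_id")
    mcols(clusters)$cluster_id <-
      vapply(clusterRows, `[[`, character(1), "cluster_id")
    mcols(clusters)$type_labels <-
      CharacterList(lapply(clusterRows, `[[`, "types"))
    mcols(clusters)$known_cluster <-
      vapply(clusterRows, `[[`, character(1), "known")
    mcols(clusters)$similarity_pct <-
      vapply(clusterRows, `[[`, numeric(1), "sim")
    truth <- do.call(rbind, lapply(species, `[[`, "truth"))
    rownames(truth) <- NULL
    list(spec = spec, refdb = refdb, certificate = ref$certificate,
         species = species, clusters = clusters, truth = truth,
         truthSummary = .truthSummary(spec, truth))
  })
}

## the Table-2-style summary implied by the truth table alone
.truthSummary <- function(spec, truth) {
  comp <- truth[truth$category == "COMPLETE", , drop = FALSE]
  planted <- comp[comp$level != "NEW_FAMILY", , drop = FALSE]
  nNewTotal <- sum(comp$level == "NEW_FAMILY")
  plantedFams <- unique(planted$family_label)
  plantedSubs <- unique(
    planted$subfamily_label[planted$level == "SUBFAMILY"])
  famCount <- table(planted$family_label)
  dominant <- if (length(famCount)) {
    mx <- max(famCount)
    sort(names(famCount)[famCount == mx])[1]
  } else NA_character_
  nSpecies <- spec@nSpecies
  totalP450 <- nrow(comp)
  totalBgcs <- nSpecies * spec@clustersPerSpecies
  totalInBgc <- sum(comp$in_bgc)
  data.frame(
    n_species = nSpecies,
    total_p450s = totalP450,
    n_families = length(plantedFams) + nNewTotal,
    n_subfamilies = length(plantedSubs) +
      sum(comp$level == "FAMILY") + nNewTotal,
    dominant_family = dominant,
    avg_p450s = roundedMean(totalP450, nSpecies),
    n_bgc_species = nSpecies,
    total_bgcs = totalBgcs,
    avg_bgcs = roundedMean(totalBgcs, nSpecies),
    total_p450s_bgc_species = totalP450,
    total_p450s_in_bgcs = totalInBgc,
    pct_p450s_in_bgcs = if (totalP450 > 0)
      truncatedPercent(totalInBgc, totalP450) else 0L,
    stringsAsFactors = FALSE)
}

#' Run the whole pipeline over a cohort bundle
#'
#' Triage per species, cohort-wide classification, BGC membership and
#' the cohort roll-up, exactly as one would run the stages by hand.
#'
#' @param cohort result of \code{\link{makeCohort}} or
#'   \code{\link{readCohortBundle}}.
#' @param scheme a \code{\linkS4class{ScoringScheme}}.
#' @param fragmentMaxLen see \code{\link{triageSequence}}.
#' @return a list with \code{triage} (per species),
#'   \code{assignments}, \code{memberships}, \code{profiles} and
#'   \code{summary}.
#' @export
runCohortPipeline <- function(cohort, scheme = ScoringScheme(),
                              fragmentMaxLen = 300) {
  triage <- lapply(cohort$species, function(s)
    triageProteome(s$proteins, fragmentMaxLen))
  keptSeqs <- character(0)
  keptSpecies <- character(0)
  for (sp in names(cohort$species)) {
    aa <- cohort$species[[sp]]$proteins
    keep <- completeP450s(aa, triage[[sp]]$calls)
    keptSeqs <- c(keptSeqs, setNames(as.character(keep), names(keep)))
    keptSpecies <- c(keptSpecies,
                     rep(sp, length(keep)))
  }
  complete <- AAStringSet(keptSeqs)
  mcols(complete)$species_id <- keptSpecies
  assignments <- classifyProteome(complete, cohort$refdb, scheme)
  genes <- unlist(GenomicRanges::GRangesList(
    lapply(cohort$species, `[[`, "genes")), use.names = FALSE)
  memberships <- linkP450s(assignments, genes, cohort$clusters)
  profiles <- speciesProfiles(assignments, memberships,
                              cohort$clusters)
  list(triage = triage, assignments = assignments,
       memberships = memberships, profiles = profiles,
       summary = cohortSummary(profiles, assignments, memberships))
}

#' Write a cohort bundle to disk
#'
#' Emits exactly the plain-text formats the readers consume: one
#' FASTA and one GFF3 per species, a reference FASTA, the cluster
#' TSV and the truth table.  Byte-identical across runs for the same
#' cohort.
#'
#' @param cohort result of \code{\link{makeCohort}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohortBundle <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeProteomeFasta(refSequences(cohort$refdb),
                     file.path(dir, "refdb.faa"))
  for (sp in names(cohort$species)) {
    writeProteomeFasta(cohort$species[[sp]]$proteins,
                       file.path(dir, paste0(sp, ".faa")))
    writeGffGenes(cohort$species[[sp]]$genes,
                  file.path(dir, paste0(sp, ".gff3")))
  }
  writeClusterTable(cohort$clusters, file.path(dir, "clusters.tsv"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort bundle from disk
#'
#' Inverse of \code{\link{writeCohortBundle}} (the spec, certificate
#' and truth summary are not round-tripped).
#'
#' @param dir bundle directory.
#' @return a list shaped like \code{\link{makeCohort}} output with
#'   elements \code{refdb}, \code{species}, \code{clusters} and
#'   \code{truth}.
#' @export
readCohortBundle <- function(dir) {
  refdb <- readReferenceFasta(file.path(dir, "refdb.faa"))
  faa <- sort(list.files(dir, pattern = "^sp.*\\.faa$"))
  species <- list()
  for (f in faa) {
    sp <- sub("\\.faa$", "", f)
    species[[sp]] <- list(
      proteins = readProteomeFasta(file.path(dir, f), sp),
      genes = readGffGenes(file.path(dir, paste0(sp, ".gff3")), sp))
  }
  truthPath <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truthPath))
    read.delim(truthPath, stringsAsFactors = FALSE) else NULL
  list(refdb = refdb, species = species,
       clusters = readClusterTable(file.path(dir, "clusters.tsv")),
       truth = truth)
}
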