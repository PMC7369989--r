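## Readers and writers for the plain-text formats the pipeline touches.
## Coordinates are 1-based inclusive (GFF3 convention) everywhere in
## the package; any 0-based input must be converted at the boundary.

#' Read a proteome FASTA file
#'
#' Sequences are uppercased, whitespace inside sequence lines is
#' stripped, and multi-line records are concatenated.  The record
#' identifier is the first whitespace-delimited token of the header.
#'
#' @param path path to a protein FASTA file.
#' @param speciesId species identifier attached to every record.
#' @return an \code{AAStringSet} named by protein id, with a
#'   \code{species_id} metadata column.  An empty file yields an
#'   empty set.
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">a", "MKV", ">b", "ACD", "EFG"), f)
#' aa <- readProteomeFasta(f, "sp1")
#' as.character(aa[["b"]])   # "ACDEFG"
#' @export
readProteomeFasta <- function(path, speciesId = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readBStringSet(path)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(raw)))
  ids <- vapply(strsplit(names(raw), "[[:space:]]+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate protein id in ", path, ": ", ids[duplicated(ids)][1])
  bad <- !grepl("^[A-Z]+$", seqs)
  if (any(bad))
    stop("sequence with characters outside A-Z: ", ids[bad][1])
  aa <- AAStringSet(setNames(seqs, ids))
  mcols(aa)$species_id <- rep(speciesId, length(aa))
  aa
}

#' Write a proteome FASTA file
#'
#' Inverse of \code{\link{readProteomeFasta}}; reading the written
#' file back is the identity on ids and sequences.
#'
#' @param aa an \code{AAStringSet} named by protein id.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProteomeFasta <- function(aa, path) {
  writeXStringSet(aa, filepath = path, width = 60L)
  invisible(path)
}

#' Read a reference database FASTA file
#'
#' The first whitespace-delimited token of every header must parse as
#' a CYP name (see \code{\link{parseCypName}}); the remainder of the
#' header is free description.
#'
#' @param path path to the reference FASTA.
#' @return a \code{\linkS4class{ReferenceDB}}.
#' @export
readReferenceFasta <- function(path) {
  aa <- readProteomeFasta(path, speciesId = "reference")
  ReferenceDB(aa)
}

#' Read gene features from a GFF3 file
#'
#' Only rows whose type (column 3) is in \code{featureKinds} are
#' returned; the gene identifier is taken from the \code{ID=}
#' attribute.  Coordinates are kept 1-based inclusive.
#'
#' @param path path to a 9-column tab-separated GFF3 file.
#' @param speciesId species identifier attached to every feature.
#' @param featureKinds feature types to keep (default gene and CDS).
#' @return a \code{GRanges} with metadata columns \code{gene_id} and
#'   \code{species_id}; seqnames are contigs, strand \code{"."} maps
#'   to \code{"*"}.
#' @export
readGffGenes <- function(path, speciesId = "unknown",
                         featureKinds = c("gene", "CDS")) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  dataRow <- !grepl("^#", lines) & nzchar(trimws(lines))
  for (ln in which(dataRow)) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9L)
      stop("GFF3 line ", ln, ": expected 9 tab-separated columns, got ",
           length(fields))
    s <- suppressWarnings(as.numeric(fields[4]))
    e <- suppressWarnings(as.numeric(fields[5]))
    if (is.na(s) || is.na(e))
      stop("GFF3 line ", ln, ": non-numeric coordinates")
    if (e < s)
      stop("GFF3 line ", ln, ": end (", e, ") is before start (", s, ")")
  }
  if (!any(dataRow)) {
    gr <- GRanges()
    mcols(gr)$gene_id <- character(0)
    mcols(gr)$species_id <- character(0)
    return(gr)
  }
  gff <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gff$type) %in% featureKinds
  gff <- gff[keep]
  ids <- gff$ID
  if (is.null(ids) || any(is.na(ids)))
    stop("GFF3 feature without an ID= attribute in ", path)
  gr <- GRanges(seqnames(gff), IRanges(start(gff), end(gff)),
                strand = strand(gff))
  mcols(gr)$gene_id <- as.character(ids)
  mcols(gr)$species_id <- rep(speciesId, length(gr))
  gr
}

#' Write gene features to a GFF3 file
#'
#' @param genes a \code{GRanges} as returned by
#'   \code{\link{readGffGenes}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGffGenes <- function(genes, path) {
  strd <- as.character(strand(genes))
  strd[strd == "*"] <- "."
  lines <- c("##gff-version 3",
             if (length(genes))
               paste(as.character(seqnames(genes)), "CypMine", "gene",
                     start(genes), end(genes), ".", strd, ".",
                     paste0("ID=", genes$gene_id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

.clusterCols <- c("species_id", "cluster_id", "contig", "start", "end",
                  "types", "known_cluster", "similarity_pct")

#' Read a BGC summary table
#'
#' Consumes the tab-separated per-cluster summary emitted by cluster
#' detection software (antiSMASH-style): coordinates, semicolon
#' separated type labels, the most similar known cluster and its
#' percent similarity.  Cluster detection itself is out of scope;
#' this table is an input format.
#'
#' @param path path to a TSV with header columns \code{species_id},
#'   \code{cluster_id}, \code{contig}, \code{start}, \code{end},
#'   \code{types}, \code{known_cluster}, \code{similarity_pct}.
#' @return a \code{GRanges} (seqnames = contig, 1-based inclusive)
#'   with metadata columns \code{species_id}, \code{cluster_id},
#'   \code{type_labels} (a \code{CharacterList}),
#'   \code{known_cluster} (\code{NA} when empty) and
#'   \code{similarity_pct} (\code{NA} when absent).
#' @export
readClusterTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, sep = "\t", colClasses = "character",
                    check.names = FALSE, quote = "")
  missing <- setdiff(.clusterCols, colnames(tab))
  if (length(missing))
    stop("cluster table is missing required column: ", missing[1])
  s <- suppressWarnings(as.numeric(tab$start))
  e <- suppressWarnings(as.numeric(tab$end))
  if (any(is.na(s)) || any(is.na(e)))
    stop("non-numeric start/end in cluster table row ",
         which(is.na(s) | is.na(e))[1])
  if (any(e < s))
    stop("cluster end before start in row ", which(e < s)[1])
  types <- strsplit(tab$types, ";", fixed = TRUE)
  if (any(lengths(types) == 0L) ||
      any(vapply(types, function(x) any(!nzchar(x)), logical(1))))
    stop("cluster table row ",
         which(lengths(types) == 0L |
               vapply(types, function(x) any(!nzchar(x)), logical(1)))[1],
         ": empty type label")
  sim <- suppressWarnings(as.numeric(tab$similarity_pct))
  simGiven <- nzchar(tab$similarity_pct)
  if (any(simGiven & is.na(sim)))
    stop("non-numeric similarity_pct in cluster table row ",
         which(simGiven & is.na(sim))[1])
  if (any(simGiven & (sim < 0 | sim > 100)))
    stop("similarity_pct outside [0,100] in cluster table row ",
         which(simGiven & (sim < 0 | sim > 100))[1])
  sim[!simGiven] <- NA_real_
  gr <- GRanges(tab$contig, IRanges(as.integer(s), as.integer(e)))
  mcols(gr)$species_id <- tab$species_id
  mcols(gr)$cluster_id <- tab$cluster_id
  mcols(gr)$type_labels <- CharacterList(types)
  mcols(gr)$known_cluster <- ifelse(nzchar(tab$known_cluster),
                                    tab$known_cluster, NA_character_)
  mcols(gr)$similarity_pct <- sim
  gr
}

#' Write a BGC summary table
#'
#' Inverse of \code{\link{readClusterTable}}.
#'
#' @param clusters a cluster \code{GRanges}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeClusterTable <- function(clusters, path) {
  kn <- clusters$known_cluster
  kn[is.na(kn)] <- ""
  sim <- clusters$similarity_pct
  simChr <- ifelse(is.na(sim), "", format(sim, trim = TRUE,
                                          scientific = FALSE))
  body <- if (length(clusters))
    paste(clusters$species_id, clusters$cluster_id,
          as.character(seqnames(clusters)), start(clusters),
          end(clusters),
          vapply(clusters$type_labels, paste, character(1),
                 collapse = ";"),
          kn, simChr, sep = "\t")
  writeLines(c(paste(.clusterCols, collapse = "\t"), body), path)
  invisible(path)
}
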