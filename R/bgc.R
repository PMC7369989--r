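## P450 membership in secondary-metabolite BGC intervals and the
## family-to-cluster-type linkage tabulation.
##
## Membership is any overlap of at least one base between the gene
## and the cluster interval on the same species and contig (both
## 1-based inclusive); strand is ignored.  Full containment is
## available behind the `overlap` flag.

#' Does a gene lie in a cluster?
#'
#' @param gene a \code{GRanges} of gene features (metadata columns
#'   \code{gene_id}, \code{species_id}).
#' @param cluster a cluster \code{GRanges} (metadata columns
#'   \code{species_id}, \code{cluster_id}, ...), recycled against
#'   \code{gene} elementwise.
#' @param overlap \code{"any"} (at least one shared base, default) or
#'   \code{"contained"} (gene fully inside the cluster).
#' @return logical vector: same species, same contig, and intervals
#'   overlapping under the chosen rule.  Strand is ignored.
#' @examples
#' g <- GenomicRanges::GRanges("c1", IRanges::IRanges(200, 800))
#' g$gene_id <- "g1"; g$species_id <- "sp1"
#' k <- GenomicRanges::GRanges("c1", IRanges::IRanges(100, 5000))
#' k$species_id <- "sp1"; k$cluster_id <- "b1"
#' geneInCluster(g, k)   # TRUE
#' @export
geneInCluster <- function(gene, cluster, overlap = c("any", "contained")) {
  overlap <- match.arg(overlap)
  sameWhere <- gene$species_id == cluster$species_id &
    as.character(seqnames(gene)) == as.character(seqnames(cluster))
  hit <- if (overlap == "any")
    start(gene) <= end(cluster) & start(cluster) <= end(gene)
  else
    start(gene) >= start(cluster) & end(gene) <= end(cluster)
  as.logical(sameWhere & hit)
}

#' Intersect classified P450 genes with BGC intervals
#'
#' Every (P450, cluster) pair whose gene overlaps the cluster yields
#' one membership; a P450 inside two overlapping clusters therefore
#' yields two memberships.
#'
#' @param assignments classification results (see
#'   \code{\link{classifyProteome}}); every \code{protein_id} must
#'   have a matching \code{gene_id} in \code{genes}.
#' @param genes gene \code{GRanges} (see \code{\link{readGffGenes}}).
#' @param clusters cluster \code{GRanges} (see
#'   \code{\link{readClusterTable}}).
#' @param overlap see \code{\link{geneInCluster}}.
#' @return a \code{DataFrame} with one row per membership:
#'   \code{species_id}, \code{protein_id}, \code{cluster_id},
#'   \code{type_labels} (\code{CharacterList}) and
#'   \code{family_label}, ordered by (species, protein, cluster).
#' @export
linkP450s <- function(assignments, genes, clusters,
                      overlap = c("any", "contained")) {
  overlap <- match.arg(overlap)
  gidx <- match(assignments$protein_id, genes$gene_id)
  if (any(is.na(gidx)))
    stop("no gene coordinates for: ",
         paste(assignments$protein_id[is.na(gidx)], collapse = ", "))
  empty <- DataFrame(species_id = character(0),
                     protein_id = character(0),
                     cluster_id = character(0),
                     type_labels = CharacterList(),
                     family_label = character(0))
  if (!nrow(assignments) || !length(clusters)) return(empty)
  pg <- genes[gidx]
  ## composite seqnames make "same species AND same contig" a plain
  ## overlap query
  key <- function(sp, ctg) paste(sp, ctg, sep = "\r")
  gKey <- key(pg$species_id, as.character(seqnames(pg)))
  cKey <- key(clusters$species_id, as.character(seqnames(clusters)))
  lv <- unique(c(gKey, cKey))
  gg <- GRanges(factor(gKey, lv), IRanges(start(pg), end(pg)))
  cc <- GRanges(factor(cKey, lv), IRanges(start(clusters), end(clusters)))
  hits <- findOverlaps(gg, cc,
                       type = if (overlap == "contained") "within"
                              else "any")
  if (!length(hits)) return(empty)
  qi <- queryHits(hits); si <- subjectHits(hits)
  out <- DataFrame(
    species_id = assignments$species_id[qi],
    protein_id = assignments$protein_id[qi],
    cluster_id = clusters$cluster_id[si],
    type_labels = clusters$type_labels[si],
    family_label = assignments$family_label[qi])
  out[order(out$species_id, out$protein_id, out$cluster_id), ]
}

#' Family-by-cluster-type linkage table
#'
#' A membership whose cluster carries k type labels (hybrid cluster)
#' contributes one count to each of its k (family, type) cells, so
#' the table total equals the sum over memberships of their label
#' counts.
#'
#' @param memberships result of \code{\link{linkP450s}}.
#' @return data.frame with columns \code{family_label},
#'   \code{type_label}, \code{n}, ordered by decreasing count then
#'   labels.
#' @export
familyBgcLinkage <- function(memberships) {
  if (!nrow(memberships))
    return(data.frame(family_label = character(0),
                      type_label = character(0), n = integer(0)))
  k <- lengths(memberships$type_labels)
  long <- data.frame(
    family_label = rep(memberships$family_label, k),
    type_label = unlist(memberships$type_labels, use.names = FALSE),
    stringsAsFactors = FALSE)
  agg <- aggregate(list(n = rep(1L, nrow(long))),
                   long[c("family_label", "type_label")], sum)
  agg <- agg[order(-agg$n, agg$family_label, agg$type_label), ]
  rownames(agg) <- NULL
  agg
}

#' Tally cluster types among P450-containing clusters
#'
#' Counts, per type label, the clusters that contain at least one
#' P450; hybrid clusters count once per label.
#'
#' @param memberships result of \code{\link{linkP450s}}.
#' @param clusters the cluster \code{GRanges} the memberships came
#'   from.
#' @return data.frame with columns \code{type_label},
#'   \code{n_clusters}, in descending count order (ties by label).
#' @export
bgcTypeTally <- function(memberships, clusters) {
  if (!nrow(memberships) || !length(clusters))
    return(data.frame(type_label = character(0),
                      n_clusters = integer(0)))
  ckey <- paste(clusters$species_id, clusters$cluster_id, sep = "\r")
  mkey <- unique(paste(memberships$species_id,
                       memberships$cluster_id, sep = "\r"))
  withP450 <- clusters[ckey %in% mkey]
  labels <- unlist(withP450$type_labels, use.names = FALSE)
  if (!length(labels))
    return(data.frame(type_label = character(0),
                      n_clusters = integer(0)))
  tab <- table(labels)
  out <- data.frame(type_label = names(tab),
                    n_clusters = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_clusters, out$type_label), ]
  rownames(out) <- NULL
  out
}
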