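## Independent oracles and shared fixtures.  Each oracle is a direct,
## unoptimised restatement of the definition it checks, kept free of
## the package code paths it validates.

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomSeq <- function(n, alphabet = .aa20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## brute-force window scans (0-based positions)
bruteExxr <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  pos <- integer(0)
  if (n >= 4)
    for (i in seq_len(n - 3L))
      if (ch[i] == "E" && ch[i + 3L] == "R") pos <- c(pos, i - 1L)
  pos
}

bruteCxg <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  pos <- integer(0)
  if (n >= 3)
    for (i in seq_len(n - 2L))
      if (ch[i] == "C" && ch[i + 2L] == "G") pos <- c(pos, i - 1L)
  pos
}

## exhaustive enumeration of every global alignment of a and b under
## an affine gap model (gap run of length L costs open + L * ext, end
## gaps included), returning the optimal score and the set of
## (n_columns, n_identical) pairs achieved by co-optimal alignments
enumerateAlignments <- function(a, b, mat, open = 10, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  st <- new.env()
  st$score <- -Inf
  st$stats <- list()
  rec <- function(i, j, score, gapState, ncol, nid) {
    if (i > length(A) && j > length(B)) {
      if (score > st$score) {
        st$score <- score
        st$stats <- list(c(ncol, nid))
      } else if (score == st$score) {
        st$stats[[length(st$stats) + 1L]] <- c(ncol, nid)
      }
      return(invisible())
    }
    if (i <= length(A) && j <= length(B))
      rec(i + 1L, j + 1L, score + mat[A[i], B[j]], 0L, ncol + 1L,
          nid + (A[i] == B[j]))
    if (i <= length(A))
      rec(i + 1L, j, score - ext - if (gapState == 1L) 0 else open,
          1L, ncol + 1L, nid)
    if (j <= length(B))
      rec(i, j + 1L, score - ext - if (gapState == 2L) 0 else open,
          2L, ncol + 1L, nid)
  }
  rec(1L, 1L, 0, 0L, 0L, 0L)
  list(score = st$score, stats = unique(st$stats))
}

blosum62 <- function() substitutionMatrixOf(ScoringScheme())

## quadratic all-pairs interval membership oracle (plain scalar
## double loop over extracted vectors)
bruteMemberships <- function(assignments, genes, clusters) {
  gi <- match(assignments$protein_id, genes$gene_id)
  gSp <- genes$species_id[gi]
  gCtg <- as.character(GenomeInfoDb::seqnames(genes))[gi]
  gS <- BiocGenerics::start(genes)[gi]
  gE <- BiocGenerics::end(genes)[gi]
  cSp <- clusters$species_id
  cCtg <- as.character(GenomeInfoDb::seqnames(clusters))
  cS <- BiocGenerics::start(clusters)
  cE <- BiocGenerics::end(clusters)
  out <- list()
  for (i in seq_len(nrow(assignments))) {
    for (j in seq_along(clusters)) {
      if (gSp[i] == cSp[j] && gCtg[i] == cCtg[j] &&
          gS[i] <= cE[j] && cS[j] <= gE[i])
        out[[length(out) + 1L]] <-
          c(assignments$protein_id[i], clusters$cluster_id[j])
    }
  }
  if (!length(out))
    return(data.frame(protein_id = character(0),
                      cluster_id = character(0)))
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("protein_id", "cluster_id")
  df[order(df$protein_id, df$cluster_id), , drop = FALSE]
}

## random gene/cluster layout for the membership property tests
randomLayout <- function(nGenes, nClusters, nSpecies = 3,
                         nContigs = 2, span = 100000L) {
  spAll <- sprintf("sp%02d", seq_len(nSpecies))
  sp <- sample(spAll, nGenes, replace = TRUE)
  ctg <- sample(sprintf("ctg%d", seq_len(nContigs)), nGenes,
                replace = TRUE)
  gs <- sample(span, nGenes, replace = TRUE)
  genes <- GenomicRanges::GRanges(
    ctg, IRanges::IRanges(gs, width = sample(200:2000, nGenes,
                                             replace = TRUE)))
  genes$gene_id <- sprintf("g%04d", seq_len(nGenes))
  genes$species_id <- sp
  csp <- sample(spAll, nClusters, replace = TRUE)
  cctg <- sample(sprintf("ctg%d", seq_len(nContigs)), nClusters,
                 replace = TRUE)
  cs <- sample(span, nClusters, replace = TRUE)
  clusters <- GenomicRanges::GRanges(
    cctg, IRanges::IRanges(cs, width = sample(5000:30000, nClusters,
                                              replace = TRUE)))
  clusters$species_id <- csp
  clusters$cluster_id <- sprintf("c%04d", seq_len(nClusters))
  clusters$type_labels <- IRanges::CharacterList(
    as.list(sample(c("terpene", "NRPS", "T1PKS"), nClusters,
                   replace = TRUE)))
  clusters$known_cluster <- rep(NA_character_, nClusters)
  clusters$similarity_pct <- rep(NA_real_, nClusters)
  assignments <- data.frame(
    species_id = sp, protein_id = genes$gene_id,
    family_label = sample(c("CYP9001", "CYP9002", "NEWF001"), nGenes,
                          replace = TRUE),
    stringsAsFactors = FALSE)
  list(assignments = assignments, genes = genes, clusters = clusters)
}

## shared small reference database (generation is seeded, so this is
## the same object in every test run)
.fixtures <- new.env()

tinyRefdb <- function() {
  if (is.null(.fixtures$refdb))
    .fixtures$refdb <- makeReferenceDb(2, 2, seed = 7)
  .fixtures$refdb
}

## assignments table shaped like classifyProteome output, for tests
## of the roll-up statistics that do not need sequences
fakeAssignments <- function(species, family, subfamily,
                            protein = sprintf("p%03d",
                                              seq_along(species))) {
  n <- length(species)
  data.frame(species_id = species, protein_id = protein,
             best_ref = rep(NA_character_, n),
             best_identity = rep(NA_real_, n),
             level = rep("SUBFAMILY", n), family_label = family,
             subfamily_label = subfamily, stringsAsFactors = FALSE)
}
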