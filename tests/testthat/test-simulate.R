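test_that("identity-targeted mutation lands within +/-2 points", {
  seed <- withr::with_seed(131, makeP450Seed(400))
  expect_identical(mutateToIdentity(seed, 100, seed = 1), seed)
  for (target in c(60, 30)) {
    mut <- mutateToIdentity(seed, target, seed = 1)
    id <- unname(sequenceIdentity(
      Biostrings::AAStringSet(c(x = mut)), seed))
    expect_true(abs(id - target) <= 2,
                info = paste("target", target, "got", id))
    # planted motifs survive mutation
    expect_gt(length(scanExxr(mut)), 0)
    expect_gt(length(scanCxg(mut)), 0)
  }
  expect_error(mutateToIdentity(strrep("A", 50), 60), "100")
})

test_that("generated reference databases honour their identity design", {
  ref <- tinyRefdb()   # makeReferenceDb(2, 2, seed = 7)
  db <- ref$refdb
  expect_equal(length(db), 4L)
  expect_equal(names(db), c("CYP9001A1", "CYP9001B1",
                            "CYP9002A1", "CYP9002B1"))
  cert <- ref$certificate
  expect_equal(nrow(cert), 6L)
  # certified: cross-family pairs below 35%
  expect_true(all(cert$identity[!cert$same_family] < 35))
  # certificate recomputation: values match a fresh aligner pass
  for (i in seq_len(nrow(cert))) {
    id <- unname(sequenceIdentity(
      refSequences(db)[cert$ref1[i]],
      as.character(refSequences(db)[[cert$ref2[i]]])))
    expect_equal(cert$identity[i], id)
  }
  # subfamily representatives sit in the 45-54% window to their seed
  ab <- cert$identity[cert$ref1 == "CYP9001A1" &
                        cert$ref2 == "CYP9001B1"]
  expect_true(ab >= 45 && ab <= 54)
  # every reference triages COMPLETE (also enforced by the validity
  # method, checked here end to end)
  calls <- triageCalls(refSequences(db))
  expect_true(all(calls$category == "COMPLETE"))

  single <- makeReferenceDb(1, 1, seed = 1)
  expect_equal(length(single$refdb), 1L)
  expect_equal(nrow(single$certificate), 0L)
})

test_that("synthetic proteomes plant recoverable categories and labels", {
  db <- tinyRefdb()$refdb
  prot <- makeProteome(
    "spT",
    complete = data.frame(ref = c("CYP9001A1", "CYP9001B1", NA),
                          identity = c(75, 48, NA)),
    refdb = db, nPseudo = 1, nFragment = 1, seed = 17)
  expect_equal(length(prot$proteins), 5L)
  tri <- triageProteome(prot$proteins)
  expect_equal(as.character(tri$calls$category), prot$truth$category)
  expect_equal(tri$summary$n_complete, 3L)
  expect_equal(tri$summary$n_pseudo, 1L)
  expect_equal(tri$summary$n_fragment, 1L)
  # classification recovers the planted design
  asg <- classifyProteome(completeP450s(prot$proteins, tri$calls), db)
  expect_equal(asg$level, c("SUBFAMILY", "FAMILY", "NEW_FAMILY"))
  expect_equal(asg$family_label[1:2], c("CYP9001", "CYP9001"))
  expect_equal(asg$subfamily_label[1], "CYP9001A")
  # genes: one per protein, non-overlapping, gene_id == protein_id
  expect_equal(prot$genes$gene_id, names(prot$proteins))
  ov <- IRanges::findOverlaps(IRanges::ranges(prot$genes))
  expect_equal(length(ov), length(prot$genes))  # self-hits only

  empty <- makeProteome("spE",
                        complete = data.frame(ref = character(0),
                                              identity = numeric(0)),
                        refdb = db, seed = 1)
  expect_equal(length(empty$proteins), 0L)
})

test_that("cohort bundles are deterministic and seed-sensitive", {
  spec <- simSpec(seed = 9, nSpecies = 2, nComplete = 4,
                  nFamilies = 2, subfamiliesPerFamily = 1,
                  clustersPerSpecies = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeCohortBundle(makeCohort(spec), d1)
  writeCohortBundle(makeCohort(spec), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 6)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  # a different seed changes sequences but not the truth-table shape
  spec2 <- simSpec(seed = 10, nSpecies = 2, nComplete = 4,
                   nFamilies = 2, subfamiliesPerFamily = 1,
                   clustersPerSpecies = 3)
  c1 <- makeCohort(spec)
  c2 <- makeCohort(spec2)
  expect_identical(dim(c1$truth), dim(c2$truth))
  expect_identical(c1$truth$category, c2$truth$category)
  expect_false(identical(as.character(c1$species$sp01$proteins),
                         as.character(c2$species$sp01$proteins)))
})

test_that("bundles round-trip through the plain-text readers", {
  spec <- simSpec(seed = 9, nSpecies = 2, nComplete = 4,
                  nFamilies = 2, subfamiliesPerFamily = 1,
                  clustersPerSpecies = 3)
  cohort <- makeCohort(spec)
  d <- withr::local_tempdir()
  writeCohortBundle(cohort, d)
  back <- readCohortBundle(d)
  expect_equal(names(back$species), names(cohort$species))
  expect_identical(as.character(back$species$sp01$proteins),
                   as.character(cohort$species$sp01$proteins))
  expect_equal(BiocGenerics::start(back$clusters),
               BiocGenerics::start(cohort$clusters))
  expect_equal(names(back$refdb), names(cohort$refdb))
  # pipeline over the re-read bundle gives the same summary
  resMem <- runCohortPipeline(cohort)
  resDisk <- runCohortPipeline(back)
  expect_equal(resDisk$summary, resMem$summary)
})

test_that("spec validity enforces the threshold exclusion bands", {
  expect_error(simSpec(subfamilyIdentityTargets = c(56, 75)),
               "bands")
  expect_error(simSpec(familyIdentityTargets = c(41, 48)), "bands")
  ok <- simSpec(stressThresholds = TRUE,
                familyIdentityTargets = c(41, 48))
  expect_s4_class(ok, "SimSpec")
  expect_error(simSpec(familyIdentityTargets = 60), "40, 55")
  expect_error(simSpec(fracInClusters = 1.5), "\\[0, 1\\]")
  expect_error(simSpec(fracInClusters = 1, clustersPerSpecies = 2),
               "clustersPerSpecies")
})
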