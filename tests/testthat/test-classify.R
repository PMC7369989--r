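## tinyRefdb(): 2 families x 2 subfamilies (CYP9001A1, CYP9001B1,
## CYP9002A1, CYP9002B1), generated once per run with a fixed seed.

test_that("an identical query lands in the reference subfamily", {
  db <- tinyRefdb()$refdb
  q <- as.character(refSequences(db)[["CYP9001A1"]])
  a <- assignCyp(q, db, proteinId = "q1")
  expect_equal(a$best_ref, "CYP9001A1")
  expect_equal(a$best_identity, 100)
  expect_equal(a$level, "SUBFAMILY")
  expect_equal(a$family_label, "CYP9001")
  expect_equal(a$subfamily_label, "CYP9001A")
})

test_that("planted identities recover the planted level", {
  db <- tinyRefdb()$refdb
  seed <- as.character(refSequences(db)[["CYP9002B1"]])
  famQ <- mutateToIdentity(seed, 48, seed = 3)
  idFam <- unname(sequenceIdentity(
    Biostrings::AAStringSet(c(x = famQ)), seed))
  expect_true(abs(idFam - 48) <= 2)
  aFam <- assignCyp(famQ, db)
  expect_equal(aFam$level, "FAMILY")
  expect_equal(aFam$family_label, "CYP9002")
  expect_true(is.na(aFam$subfamily_label))

  withr::with_seed(4, {
    newQ <- randomSeq(400)
  })
  idsNew <- sequenceIdentity(db, newQ)
  expect_true(all(idsNew < 35))
  aNew <- assignCyp(newQ, db)
  expect_equal(aNew$level, "NEW_FAMILY")
  expect_true(is.na(aNew$family_label))
})

test_that("thresholds are strict: exactly 55 is FAMILY, exactly 40 NEW_FAMILY", {
  ref <- withr::with_seed(101, makeP450Seed(400))
  subsAt <- function(s, m, seed) withr::with_seed(seed, {
    ch <- strsplit(s, "")[[1]]
    for (p in sample(length(ch), m))
      ch[p] <- sample(setdiff(.aa20, ch[p]), 1)
    paste(ch, collapse = "")
  })
  q40 <- subsAt(ref, 240, 103)
  q55 <- subsAt(ref, 180, 203)
  db <- ReferenceDB(Biostrings::AAStringSet(c(CYP9101A1 = ref)))
  a40 <- assignCyp(q40, db)
  expect_equal(a40$best_identity, 40)   # construction check
  expect_equal(a40$level, "NEW_FAMILY")
  a55 <- assignCyp(q55, db)
  expect_equal(a55$best_identity, 55)
  expect_equal(a55$level, "FAMILY")
  expect_equal(a55$family_label, "CYP9101")
})

test_that("assignment level is monotone in best identity", {
  db <- tinyRefdb()$refdb
  seed <- as.character(refSequences(db)[["CYP9001A1"]])
  levels <- vapply(c(30, 48, 75), function(t) {
    q <- mutateToIdentity(seed, t, seed = t)
    assignCyp(q, db)$level
  }, character(1))
  expect_equal(levels, c("NEW_FAMILY", "FAMILY", "SUBFAMILY"))
})

test_that("equal best hits break ties to the smaller reference name", {
  s <- withr::with_seed(71, makeP450Seed(400))
  db <- ReferenceDB(Biostrings::AAStringSet(
    c(CYP9202A1 = s, CYP9101A1 = s)))
  a <- assignCyp(s, db)
  expect_equal(a$best_ref, "CYP9101A1")
})

test_that("an empty reference database is an error", {
  db <- tinyRefdb()$refdb
  expect_error(assignCyp("ACDE", db[integer(0)]), "empty")
})

test_that("new-family placeholders merge by the >40% relation", {
  withr::with_seed(81, {
    a <- makeP450Seed(400)
    b <- mutateToIdentity(a, 80)      # same placeholder family as a
    c3 <- makeP450Seed(400)           # unrelated
  })
  idAB <- unname(sequenceIdentity(Biostrings::AAStringSet(c(x = a)),
                                  b))
  idAC <- unname(sequenceIdentity(Biostrings::AAStringSet(c(x = a)),
                                  c3))
  expect_true(idAB > 55)
  expect_true(idAC < 40)
  seqs <- Biostrings::AAStringSet(c(q1 = a, q2 = b, q3 = c3))
  asg <- data.frame(
    species_id = "sp1", protein_id = c("q1", "q2", "q3"),
    best_ref = NA, best_identity = 20, level = "NEW_FAMILY",
    family_label = NA_character_, subfamily_label = NA_character_,
    stringsAsFactors = FALSE)
  out <- allocatePlaceholders(asg, seqs)
  expect_equal(out$family_label, c("NEWF001", "NEWF001", "NEWF002"))
  # a and b also share >55%, so they share the placeholder subfamily
  expect_equal(out$subfamily_label,
               c("NEWF001A", "NEWF001A", "NEWF002A"))
})

test_that("single and distant new families get sequential placeholders", {
  withr::with_seed(82, {
    a <- makeP450Seed(400)
    b <- makeP450Seed(400)
  })
  expect_true(unname(sequenceIdentity(
    Biostrings::AAStringSet(c(x = a)), b)) < 40)
  seqs <- Biostrings::AAStringSet(c(q1 = a, q2 = b))
  asg <- data.frame(
    species_id = "sp1", protein_id = c("q1", "q2"),
    best_ref = NA, best_identity = 20, level = "NEW_FAMILY",
    family_label = NA_character_, subfamily_label = NA_character_,
    stringsAsFactors = FALSE)
  out <- allocatePlaceholders(asg, seqs)
  expect_equal(out$family_label, c("NEWF001", "NEWF002"))

  one <- allocatePlaceholders(asg[1, ], seqs)
  expect_equal(one$family_label, "NEWF001")
  expect_equal(one$subfamily_label, "NEWF001A")
})

test_that("family-level queries get per-family new-subfamily placeholders", {
  db <- tinyRefdb()$refdb
  seed <- as.character(refSequences(db)[["CYP9001A1"]])
  q1 <- mutateToIdentity(seed, 45, seed = 91)
  q2 <- mutateToIdentity(seed, 50, seed = 92)
  seqs <- Biostrings::AAStringSet(c(qa = q1, qb = q2))
  S4Vectors::mcols(seqs)$species_id <- c("sp1", "sp1")
  out <- classifyProteome(seqs, db)
  expect_equal(out$level, c("FAMILY", "FAMILY"))
  expect_true(all(grepl("^CYP9001-newSF[0-9]+$",
                        out$subfamily_label)))
  # mutual identity ~25% < 55 so the two found distinct subfamilies
  expect_equal(length(unique(out$subfamily_label)), 2L)
})

test_that("placeholder allocation refuses unsorted assignments", {
  seqs <- Biostrings::AAStringSet(c(q1 = "ACDE", q2 = "ACDF"))
  asg <- data.frame(
    species_id = "sp1", protein_id = c("q2", "q1"),
    best_ref = NA, best_identity = 20, level = "NEW_FAMILY",
    family_label = NA_character_, subfamily_label = NA_character_,
    stringsAsFactors = FALSE)
  expect_error(allocatePlaceholders(asg, seqs), "sorted")
})

test_that("classifyProteome on empty input returns an empty frame", {
  out <- classifyProteome(Biostrings::AAStringSet(), tinyRefdb()$refdb)
  expect_equal(nrow(out), 0L)
  expect_true(all(c("species_id", "protein_id", "level",
                    "family_label", "subfamily_label") %in%
                  colnames(out)))
})
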