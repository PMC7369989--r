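test_that("printed-table arithmetic conventions hold", {
  expect_equal(roundedMean(5460, 203), 27L)
  expect_equal(roundedMean(4457, 144), 31L)
  expect_equal(roundedMean(0, 5), 0L)
  expect_equal(roundedMean(7, 2), 4L)        # half away from zero
  expect_equal(roundedMean(-7, 2), -4L)
  expect_error(roundedMean(5, 0), "at least 1")

  expect_equal(truncatedPercent(1231, 5460), 22L)
  expect_equal(truncatedPercent(204, 1784), 11L)
  expect_equal(truncatedPercent(10, 10), 100L)
  expect_equal(truncatedPercent(0, 7), 0L)
  expect_error(truncatedPercent(5, 0), "at least 1")
  expect_error(truncatedPercent(11, 10), "exceeds")
})

test_that("integer average and percentage agree with exact rational oracles", {
  withr::with_seed(121, {
    total <- sample(0:10000, 2000, replace = TRUE)
    n <- sample(1:500, 2000, replace = TRUE)
    for (i in seq_len(2000)) {
      q <- total[i] / n[i]
      # rational oracle: compare twice the remainder with the divisor
      r2 <- 2L * (total[i] %% n[i])
      oracleMean <- total[i] %/% n[i] + (r2 >= n[i])
      expect_identical(roundedMean(total[i], n[i]),
                       as.integer(oracleMean))
      part <- sample(0:total[i], 1)
      if (total[i] >= 1) {
        oraclePct <- (100L * part) %/% total[i]
        expect_identical(truncatedPercent(part, total[i]),
                         as.integer(oraclePct))
      }
    }
  })
})

test_that("modal count ties break to the smallest value", {
  expect_equal(modalCount(c(1, 2, 2, 3)), 2L)
  expect_equal(modalCount(c(1, 1, 2, 2)), 1L)
  expect_equal(modalCount(7), 7L)
  expect_error(modalCount(integer(0)), "empty")
  expect_equal(countRange(c(3, 1, 2)), c(min = 1L, max = 3L))
  expect_equal(countRange(7), c(min = 7L, max = 7L))
  expect_error(countRange(numeric(0)), "empty")
})

test_that("species profiles aggregate counts, label sets and BGC hits", {
  asg <- fakeAssignments(
    species = c("sp1", "sp1", "sp1", "sp2"),
    family = c("CYP107", "CYP107", "CYP105", "CYP107"),
    subfamily = c("CYP107A", "CYP107B", "CYP105A", "CYP107A"))
  m <- S4Vectors::DataFrame(species_id = c("sp1", "sp1"),
                            protein_id = c("p001", "p001"),
                            cluster_id = c("b1", "b2"))
  k <- GenomicRanges::GRanges(c("c1", "c1", "c2"),
                              IRanges::IRanges(1, 10))
  k$species_id <- c("sp1", "sp1", "sp2")
  k$cluster_id <- c("b1", "b2", "b3")
  prof <- speciesProfiles(asg, m, k)
  expect_equal(prof$species_id, c("sp1", "sp2"))
  expect_equal(prof$n_p450, c(3L, 1L))
  expect_equal(prof$family_labels[[1]], c("CYP105", "CYP107"))
  expect_equal(prof$subfamily_labels[[1]],
               c("CYP105A", "CYP107A", "CYP107B"))
  # a P450 in two clusters counts once
  expect_equal(prof$n_in_bgc, c(1L, 0L))
  expect_equal(prof$n_bgc, c(2L, 1L))
  expect_true(all(prof$bgc_analyzed))
  # every species: subfamilies at least as numerous as families
  expect_true(all(lengths(prof$subfamily_labels) >=
                  lengths(prof$family_labels)))
})

test_that("presence matrix encodes presence 3 / absence -3", {
  asg <- fakeAssignments(species = c("sp1"), family = "CYP107",
                         subfamily = "CYP107A")
  prof <- speciesProfiles(asg)
  m <- presenceMatrix(prof, c("CYP107", "CYP105"))
  expect_equal(as.vector(m), c(3L, -3L))
  expect_equal(colnames(m), c("CYP107", "CYP105"))
  expect_error(presenceMatrix(prof, "CYP105"), "missing")

  asg2 <- fakeAssignments(species = c("sp1", "sp2"),
                          family = c("CYP107", "CYP105"),
                          subfamily = c("CYP107A", "CYP105A"))
  m2 <- presenceMatrix(speciesProfiles(asg2))
  expect_true(all(m2 %in% c(3L, -3L)))
  expect_equal(dim(m2), c(2L, 2L))
  expect_equal(m2["sp1", "CYP107"], 3L)
  expect_equal(m2["sp1", "CYP105"], -3L)
})

test_that("family tally and conserved families behave", {
  asg <- fakeAssignments(
    species = c("sp1", "sp1", "sp1", "sp2"),
    family = c("CYP107", "CYP107", "CYP105", "CYP107"),
    subfamily = c("CYP107A", "CYP107B", "CYP105A", "CYP107A"))
  tal <- familyTally(asg)
  expect_equal(tal$family_label, c("CYP107", "CYP105"))
  expect_equal(tal$n, c(3L, 1L))
  expect_equal(sum(tal$n), nrow(asg))
  expect_equal(nrow(familyTally(asg[integer(0), ])), 0L)

  prof <- speciesProfiles(asg)
  expect_equal(conservedFamilies(prof), "CYP107")
  expect_equal(conservedFamilies(prof[1, ]), c("CYP105", "CYP107"))
})

test_that("subfamily diversity counts distinct subfamilies per family", {
  asg <- fakeAssignments(
    species = rep("sp1", 3),
    family = rep("CYP157", 3),
    subfamily = c("CYP157A", "CYP157A", "CYP157C"))
  d <- subfamilyDiversity(asg)
  expect_equal(d$byFamily$family_label, "CYP157")
  expect_equal(d$byFamily$n_subfamilies, 2L)
  expect_equal(d$byFamily$n_members, 3L)
  expect_equal(d$bySubfamily$n_members, c(2L, 1L))
  expect_equal(nrow(subfamilyDiversity(asg[0, ])$byFamily), 0L)
})

test_that("cohort summary reproduces its own printed-total arithmetic", {
  asg <- fakeAssignments(
    species = c("sp1", "sp1", "sp2"),
    family = c("CYP107", "CYP105", "CYP107"),
    subfamily = c("CYP107A", "CYP105A", "CYP107B"))
  k <- GenomicRanges::GRanges(rep("c1", 3), IRanges::IRanges(1, 10))
  k$species_id <- c("sp1", "sp1", "sp2")
  k$cluster_id <- c("b1", "b2", "b3")
  m <- S4Vectors::DataFrame(species_id = "sp1", protein_id = "p001",
                            cluster_id = "b1")
  prof <- speciesProfiles(asg, m, k)
  cs <- cohortSummary(prof, asg, m)
  expect_equal(cs$n_species, 2L)
  expect_equal(cs$total_p450s, 3L)
  expect_equal(cs$n_families, 2L)
  expect_equal(cs$n_subfamilies, 3L)
  expect_equal(cs$dominant_family, "CYP107")
  expect_equal(cs$avg_p450s, roundedMean(3, 2))
  expect_equal(cs$total_bgcs, 3L)
  expect_equal(cs$pct_p450s_in_bgcs, truncatedPercent(1, 3))
  expect_error(
    cohortSummary(prof, asg,
                  S4Vectors::DataFrame(species_id = "sp1",
                                       protein_id = "ghost",
                                       cluster_id = "b1")),
    "unknown proteins")
})

test_that("cohort summary is invariant to species order", {
  asg <- fakeAssignments(
    species = c("sp1", "sp2", "sp3", "sp3"),
    family = c("CYP107", "CYP105", "CYP107", "CYP9001"),
    subfamily = c("CYP107A", "CYP105A", "CYP107B", "CYP9001A"))
  prof <- speciesProfiles(asg)
  s1 <- cohortSummary(prof, asg)
  perm <- asg[c(4, 2, 3, 1), ]
  s2 <- cohortSummary(speciesProfiles(perm), perm)
  expect_equal(s1, s2)
})

test_that("a single empty species yields a zero summary", {
  asg <- fakeAssignments(character(0), character(0), character(0),
                         protein = character(0))
  prof <- speciesProfiles(asg, bgcSpecies = "sp1")
  cs <- cohortSummary(prof, asg)
  expect_equal(cs$total_p450s, 0L)
  expect_equal(cs$avg_p450s, 0L)
  expect_equal(cs$pct_p450s_in_bgcs, 0L)
})
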