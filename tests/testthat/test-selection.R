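test_that("codon site fractions follow the mitochondrial code", {
  # TTT (Phe): only TTT->TTC silent, so 1/3 synonymous site
  expect_equal(countSynNonsynSites("TTT")$synSites, 1 / 3)
  # GGG (Gly): fourfold-degenerate third position
  s <- countSynNonsynSites("GGG")
  expect_equal(s$synSites, 1)
  # identical codons: per-sequence averaging leaves sites unchanged
  m <- matrix("ATG", nrow = 4, ncol = 5)
  ca <- codonAlnFromMatrix(m)
  one <- countSynNonsynSites("ATG")
  all4 <- countSynNonsynSites(ca)
  expect_equal(all4$synSites, 5 * one$synSites)
  expect_equal(all4$nonsynSites, 5 * one$nonsynSites)
})

test_that("codon differences honor table 2 and pathway averaging", {
  expect_equal(unname(countCodonDifferences("ATT", "ATC")), c(0, 1))
  # ATA = Met under the mitochondrial code: silent vs ATG
  expect_equal(unname(countCodonDifferences("ATA", "ATG")), c(0, 1))
  expect_equal(unname(countCodonDifferences("AAA", "AAA")), c(0, 0))
  # two-step difference averaged over both pathways
  d <- countCodonDifferences("TTT", "GTA")
  expect_equal(sum(d), 2)
  # symmetry
  set.seed(5)
  codons <- names(Biostrings::getGeneticCode("2"))
  for (i in 1:25) {
    ab <- sample(codons, 2)
    expect_equal(suppressWarnings(countCodonDifferences(ab[1], ab[2])),
                 suppressWarnings(countCodonDifferences(ab[2], ab[1])))
  }
})

test_that("per-codon site identity holds over all 64 codons", {
  tab <- porpopgen:::codonTables("2")
  total <- tab$synSites + tab$nonsynSites + tab$stopFrac
  expect_equal(unname(total), rep(3, 64))
  for (cod in names(tab$synSites)) {
    o <- oracleCodonSites(cod)
    expect_equal(tab$synSites[[cod]], o[["syn"]])
    expect_equal(tab$nonsynSites[[cod]], o[["nonsyn"]])
  }
})

test_that("piN/piS matches per-codon sums and flags undefined ratios", {
  # two sequences: numerators must equal the summed per-codon differences
  set.seed(8)
  codons <- names(Biostrings::getGeneticCode("2"))
  m <- rbind(sample(codons, 30, replace = TRUE),
             sample(codons, 30, replace = TRUE))
  ca <- codonAlnFromMatrix(m)
  res <- suppressWarnings(piNpiS(ca))
  exp <- c(0, 0)
  for (j in seq_len(ncol(m))) {
    d <- suppressWarnings(countCodonDifferences(m[1, j], m[2, j]))
    if (!anyNA(d)) exp <- exp + d
  }
  expect_equal(res$meanNonsynDiffs, exp[[1]])
  expect_equal(res$meanSynDiffs, exp[[2]])

  # only synonymous variation: piN = 0, ratio 0
  m2 <- matrix("ATT", 3, 10); m2[2, 4] <- "ATC"
  r2 <- piNpiS(codonAlnFromMatrix(m2))
  expect_equal(r2$piN, 0)
  expect_equal(r2$ratio, 0)

  # single nonsynonymous difference: piS = 0 -> flagged, no error
  m3 <- matrix("ATT", 2, 300); m3[2, 7] <- "GTT"
  r3 <- piNpiS(codonAlnFromMatrix(m3))
  expect_false(r3$ratioDefined)
  expect_true(is.na(r3$ratio))
})

test_that("McDonald-Kreitman arithmetic, classification and neutral NI", {
  # constructed counts: NI = (4/5)/(2/10) = 4
  tab <- c(Dn = 2, Ds = 10, Pn = 4, Ps = 5)
  ni <- (tab[["Pn"]] / tab[["Ps"]]) / (tab[["Dn"]] / tab[["Ds"]])
  expect_equal(ni, 4)

  # engine-level check on a constructed alignment: one fixed synonymous,
  # one fixed nonsynonymous, one polymorphic synonymous, one polymorphic
  # nonsynonymous codon
  ing <- matrix("ATT", 4, 6)
  ing[, 2] <- "ATC"            # fixed difference vs outgroup ATT (syn)
  ing[, 3] <- "GTT"            # fixed difference (nonsyn)
  ing[3, 4] <- "ATC"           # polymorphic syn
  ing[2, 5] <- "GTT"           # polymorphic nonsyn
  outg <- matrix("ATT", 1, 6)
  mk <- mkTest(codonAlnFromMatrix(ing), codonAlnFromMatrix(outg))
  expect_equal(unname(mk$table), c(1, 1, 1, 1))
  expect_equal(mk$NI, 1)
  expect_lt(abs(mk$G), 1e-10)
  expect_equal(mk$interpretation, "neutral")

  # codon both polymorphic and divergent counts as polymorphism only
  ing2 <- ing
  ing2[, 6] <- c("AGT", "AGC", "AGT", "AGT")  # polymorphic AND != outgroup
  mk2 <- mkTest(codonAlnFromMatrix(ing2), codonAlnFromMatrix(outg))
  expect_equal(mk2$table[["Dn"]], 1)          # no extra fixed difference
  expect_equal(mk2$table[["Ds"]], 1)

  # undefined NI when Ds = 0, counts still reported
  ing3 <- matrix("ATT", 4, 3); ing3[, 1] <- "GTT"; ing3[2, 2] <- "ATC"
  mk3 <- mkTest(codonAlnFromMatrix(ing3), codonAlnFromMatrix(matrix("ATT",
                                                                    1, 3)))
  expect_false(mk3$NIdefined)
  expect_true(is.na(mk3$NI))
  expect_equal(mk3$table[["Dn"]], 1)
})

test_that("permutation group test calibrates and separates", {
  set.seed(3)
  # identical distributions (cloned values): p near 1
  v <- rep(c(1, 2, 3, 4), 2)
  l <- rep(c("a", "b"), each = 4)
  res <- permutationGroupTest(v, l, nPerm = 499, seed = 1)
  expect_gt(res$pvalue, 0.5)

  # two groups 10 pooled SDs apart
  v2 <- c(rnorm(10, 0, 1), rnorm(10, 10, 1))
  l2 <- rep(c("a", "b"), each = 10)
  res2 <- permutationGroupTest(v2, l2, nPerm = 1999, seed = 2)
  expect_lte(res2$pvalue, 0.001)
  expect_equal(nrow(res2$pairwise), 1L)
  expect_true(all(res2$pairwise$p_adj >= res2$pairwise$p - 1e-12))

  # under-sized groups are excluded with a warning
  expect_warning(
    res3 <- permutationGroupTest(c(v2, 5), c(l2, "c"), nPerm = 99, seed = 1),
    "excluded")
  expect_setequal(unique(c(res3$pairwise$group1, res3$pairwise$group2)),
                  c("a", "b"))
})

test_that("Pearson correlation wrapper handles edge cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlationTest(x, x)$r, 1)
  expect_equal(correlationTest(x, -x)$r, -1)
  flat <- correlationTest(x, rep(1, 5))
  expect_false(flat$defined)
  expect_error(correlationTest(1:2, 1:2), class = "porpopgen_input_error")
})
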