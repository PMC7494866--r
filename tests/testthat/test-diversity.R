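test_that("site summary matches hand-derived column scans", {
  ss <- siteSummary(makeAln(c("AAAA", "AAAT", "AATT")))
  expect_equal(ss[c("S", "singletons", "sharedPoly", "usableSites")],
               list(S = 2L, singletons = 2L, sharedPoly = 0L,
                    usableSites = 4L))

  ss2 <- siteSummary(makeAln(c("AACC", "AACC", "TTCC", "TTCC")))
  expect_equal(ss2$S, 2L)
  expect_equal(ss2$singletons, 0L)
  expect_equal(ss2$sharedPoly, 2L)

  # gap / ambiguity columns drop for everyone (complete deletion)
  ss3 <- siteSummary(makeAln(c("A-CT", "AACA", "ANCT")))
  expect_equal(ss3$usableSites, 3L)   # column 2 excluded for everyone
  expect_equal(ss3$S, 1L)

  expect_error(siteSummary(makeAln("ACGT")),
               class = "porpopgen_degenerate_error")
  expect_error(siteSummary(makeAln(c("NN", "NN"))),
               class = "porpopgen_degenerate_error")
})

test_that("haplotype summary follows the Nei formulas", {
  hs <- haplotypeSummary(makeAln(c("AAAA", "AAAT", "AATT")))
  expect_equal(hs$H, 3L)
  expect_equal(hs$Hd, 1)
  hs2 <- haplotypeSummary(makeAln(c("AAAA", "AAAA", "AAAT")))
  expect_equal(hs2$H, 2L)
  expect_equal(hs2$Hd, 2 / 3)
  hs3 <- haplotypeSummary(makeAln(c("ACGT", "ACGT", "ACGT")))
  expect_equal(hs3$H, 1L)
  expect_equal(hs3$Hd, 0)
  # sequences differing only at an excluded column collapse
  hs4 <- haplotypeSummary(makeAln(c("ACG-", "ACGT")))
  expect_equal(hs4$H, 1L)
})

test_that("nucleotide diversity equals the all-pairs mean", {
  nd <- nucleotideDiversity(makeAln(c("AAAA", "AAAT", "AATT")))
  expect_equal(nd$piPerSite, (1 + 2 + 1) / 3 / 4)
  expect_equal(nd$piTotal, 4 / 3)
  expect_equal(nucleotideDiversity(
    makeAln(c("ACGT", "ACGT")))$piPerSite, 0)
})

test_that("Watterson's theta uses the harmonic normalizer", {
  expect_equal(wattersonTheta(2, 3, 4), 2 / (1.5 * 4))
  expect_equal(wattersonTheta(0, 5, 100), 0)
  expect_equal(wattersonTheta(3, 2, 10), 3 / 10)  # a1 = 1 at n = 2
})

test_that("diversity statistics match the brute-force oracle on random data", {
  set.seed(42)
  for (rep in 1:40) {
    aln <- randomAln(sample(2:6, 1), sample(8:60, 1),
                     pGap = sample(c(0, 0.05), 1))
    o <- oracleDiversity(aln)
    if (o$usable == 0L) next
    ss <- siteSummary(aln)
    hs <- haplotypeSummary(aln)
    nd <- nucleotideDiversity(aln)
    expect_equal(ss$S, o$S)
    expect_equal(ss$singletons, o$singletons)
    expect_equal(ss$sharedPoly, o$shared)
    expect_equal(ss$S, ss$singletons + ss$sharedPoly)  # invariant
    expect_equal(hs$H, o$H)
    expect_equal(hs$Hd, o$Hd)
    expect_equal(nd$piTotal, o$piTotal)
    expect_equal(wattersonTheta(ss$S, nSequences(aln), ss$usableSites),
                 o$thetaW)
  }
})

test_that("pi from the site-frequency spectrum equals the pairwise form", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    g <- simulateGenealogy(n)
    mat <- dropMutations(g, theta = 6)
    if (ncol(mat) == 0L) next
    counts <- colSums(mat)
    sfsPi <- sum(2 * counts * (n - counts) / (n * (n - 1)))
    # pairwise: mean Hamming distance
    d <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d <- d + sum(mat[i, ] != mat[j, ])
    expect_equal(sfsPi, d / choose(n, 2))
  }
})

test_that("rarefaction is deterministic, degenerate at n = k, and unbiased", {
  set.seed(9)
  aln <- randomAln(5, 60)
  r1 <- rarefiedPi(aln, k = 3, B = 200, seed = 11)
  r2 <- rarefiedPi(aln, k = 3, B = 200, seed = 11)
  expect_identical(r1$piValues, r2$piValues)

  aln3 <- randomAln(3, 40)
  r3 <- rarefiedPi(aln3, k = 3, B = 50, seed = 1)
  expect_equal(r3$ciHigh - r3$ciLow, 0)
  expect_equal(stats::var(r3$piValues), 0)

  # mean over replicates approaches the exhaustive C(5,3) enumeration
  subsets <- utils::combn(5, 3)
  codes <- porpopgen:::baseCodeMatrix(aln)
  exact <- mean(apply(subsets, 2L, function(ix)
    porpopgen:::piFromCodes(codes[ix, , drop = FALSE])))
  r5 <- rarefiedPi(aln, k = 3, B = 3000, seed = 2)
  se <- stats::sd(r5$piValues) / sqrt(r5$B)
  expect_lt(abs(r5$mean - exact), 4 * se + 1e-12)

  expect_error(rarefiedPi(aln3, k = 4), class = "porpopgen_degenerate_error")
})

test_that("region diversity profiles constraint classes", {
  # variation confined to the unannotated (noncoding) tail
  aln <- makeAln(c("ACGTACGTAAAA", "ACGTACGTAAAT", "ACGTACGTAATT"))
  ann <- geneAnnotation(c("g", "t"), c(1, 7), c(6, 8), c("+", "+"),
                        c("CDS", "tRNA"))
  rd <- regionDiversity(aln, ann)
  expect_equal(rd$pi[rd$klass == "CDS"], 0)
  expect_gt(rd$pi[rd$klass == "noncoding"], 0)
  # all-identical alignment: every present class is 0
  rd0 <- regionDiversity(makeAln(c("ACGTACGTAAAA", "ACGTACGTAAAA")), ann)
  expect_true(all(rd0$pi == 0))
})

test_that("diversity table iterates groups and partitions", {
  synth <- suppressWarnings(synthMitogenomeSet(
    groups = data.frame(species = c("Pp", "Pp"), lineage = c("A", "B"),
                        n = c(5, 3), theta1 = c(8, 2)),
    genomeLength = 16302L, seed = 21))
  tab <- diversityTable(synth$alignment, synth$lineages, synth$ann,
                        partitions = c("whole", "cds_concat"))
  expect_setequal(unique(tab$partition), c("whole", "cds_concat"))
  # lineages A, B plus the species aggregate
  expect_setequal(unique(tab$lineage), c("A", "B", "(all)"))
  expect_true(all(tab$S == tab$singletons + tab$shared_poly))
  expect_true(all(tab$Hd >= 0 & tab$Hd <= 1))
  expect_true(all(tab$H >= 1 & tab$H <= tab$n))
})
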