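test_that("Tajima's D is zero when pi equals the Watterson expectation", {
  # n = 4: 8 singleton columns + 3 doubleton columns give
  # pi_total = 8*(1/2) + 3*(2/3) = 6 = S/a1 exactly (a1 = 11/6)
  base <- matrix("A", 4, 11)
  for (j in 1:8) base[(j %% 4) + 1, j] <- "T"
  for (j in 9:11) base[1:2, j] <- "T"
  aln <- makeAln(apply(base, 1, paste, collapse = ""))
  expect_equal(tajimasD(aln), 0)
  expect_error(tajimasD(makeAln(c("AT", "AA", "TA"))),
               class = "porpopgen_degenerate_error")
})

test_that("SFS statistics agree with independent oracles on random data", {
  set.seed(12)
  for (rep in 1:60) {
    n <- sample(4:9, 1)
    aln <- randomAln(n, sample(20:60, 1))
    o <- oracleDiversity(aln)
    if (o$S < 1) next
    oe <- oracleEta(aln)
    expect_equal(tajimasD(aln), oracleTajimaD(o$piTotal, o$S, n),
                 tolerance = 1e-12)
    fl <- fuLiTests(aln)
    ofl <- oracleFuLi(oe$eta, oe$etaS, o$piTotal, n)
    expect_equal(fl$dstar, ofl$dstar, tolerance = 1e-12)
    expect_equal(fl$fstar, ofl$fstar, tolerance = 1e-12)
  }
})

test_that("Fu & Li statistics respond to the singleton spectrum", {
  # all mutations singletons: D* and F* negative
  m <- matrix("A", 6, 12)
  for (j in 1:12) m[(j %% 6) + 1, j] <- "C"
  fl <- fuLiTests(makeAln(apply(m, 1, paste, collapse = "")))
  expect_equal(fl$etaS, 12L)
  expect_lt(fl$dstar, 0)
  expect_lt(fl$fstar, 0)
  # balanced mid-frequency variants, no singletons: D* positive
  m2 <- matrix("A", 6, 8)
  for (j in 1:8) m2[1:3, j] <- "C"
  fl2 <- fuLiTests(makeAln(apply(m2, 1, paste, collapse = "")))
  expect_equal(fl2$etaS, 0L)
  expect_gt(fl2$dstar, 0)
})

test_that("simulation p-values are two-tailed and centred at the null", {
  null <- porpopgen:::simulateNullStats(10, 8, 800, seed = 31)
  med <- stats::median(null$D)
  p <- porpopgen:::twoTailedP(med, null$D)
  expect_gt(p, 0.8)
  expect_lte(p, 1)
  pLow <- neutralityPvalue("tajima_d", -3, n = 10, S = 8, nSims = 400,
                           seed = 5)
  expect_lt(pLow, 0.05)
})

test_that("expected mismatch distributions match the closed forms", {
  f <- mismatchExpected("constant", 1, maxK = 6)
  expect_equal(f[1], 0.5)
  expect_equal(f[2], 0.25)
  # normalization with long tail
  expect_equal(sum(mismatchExpected("constant", 4, maxK = 3000)), 1,
               tolerance = 1e-9)
  # limit cases of the expansion model
  e0 <- mismatchExpected("sudden_expansion", 2, 40, 0, maxK = 15)
  expect_equal(as.numeric(e0),
               as.numeric(mismatchExpected("constant", 2, maxK = 15)))
  eInf <- mismatchExpected("sudden_expansion", 2, 40, 1e3, maxK = 15)
  expect_equal(as.numeric(eInf),
               as.numeric(mismatchExpected("constant", 40, maxK = 15)),
               tolerance = 1e-8)
  expect_error(mismatchExpected("constant", Inf),
               class = "porpopgen_input_error")
})

test_that("observed mismatch histograms count pairs over usable columns", {
  aln <- makeAln(c("AAAA", "AAAT", "AATT"))
  h <- mismatchHistogram(aln)
  # pairs differ by 1, 2, 1 -> histogram at k=1: 2 pairs, k=2: 1 pair
  expect_equal(h, c(0L, 2L, 1L))
  expect_equal(sum(h), choose(3, 2))
})

test_that("noiseless mismatch refits recover the generating parameters", {
  n <- 25
  f <- mismatchExpected("sudden_expansion", 1, 80, 4, maxK = 50)
  obs <- f / sum(f) * choose(n, 2)
  fit <- fitSuddenExpansion(obs, B = 0)
  expect_lt(abs(fit@tau - 4) / 4, 1e-3)
  expect_lt(abs(fit@theta0 - 1), 0.02)
  expect_true(fit@converged)
})

test_that("monomorphic histograms collapse to the tau = 0 boundary", {
  fit <- fitSuddenExpansion(c(choose(5, 2)), B = 0)
  expect_equal(fit@tau, 0)
  expect_equal(fit@ssd, 0)
})

test_that("parametric bootstrap produces ordered CIs and a p-value", {
  set.seed(44)
  model <- demographyModel("sudden_expansion", 1, 60, 5)
  g <- simulateGenealogy(20, model)
  mc <- porpopgen:::mutationCarrierCounts(g, theta = 60, carriers = TRUE)
  h <- porpopgen:::mismatchFromCarriers(mc$carriers, 20)
  fit <- fitSuddenExpansion(h, B = 60, seed = 3)
  expect_equal(nrow(fit@ci), 3L)
  expect_true(all(fit@ci[, "lower"] <= fit@ci[, "upper"]))
  expect_gte(fit@pSsd, 0)
  expect_lte(fit@pSsd, 1)
  # same seed, same result
  fit2 <- fitSuddenExpansion(h, B = 60, seed = 3)
  expect_equal(fit@ci, fit2@ci)
  expect_equal(fit@pSsd, fit2@pSsd)
})

test_that("mutational-unit conversions follow tau = 2 mu t", {
  conv <- tauToTime(4, 5e-8, 16302, 10)
  expect_equal(conv$tYears, 4 / (2 * 5e-8 * 16302 * 10) * 10,
               tolerance = 1e-12)
  expect_equal(conv$tYears, 2453.687, tolerance = 1e-4)
  expect_equal(tauToTime(0, 5e-8, 16302, 10)$tYears, 0)
  # doubling the rate halves the time
  expect_equal(tauToTime(4, 1e-7, 16302, 10)$tYears,
               conv$tYears / 2)
  expect_equal(thetaToNe(10, 0.001), 5000)
  expect_error(tauToTime(4, -1, 10, 10), class = "porpopgen_input_error")
})
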