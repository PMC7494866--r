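# Site-frequency-spectrum neutrality tests with coalescent-simulation
# p-values, and mismatch-distribution demographic inference under the
# constant-size and sudden-expansion models.

tajimaCoefficients <- function(n) {
  a1 <- harmonicA1(n); a2 <- harmonicA2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

tajimaDFromStats <- function(piTotal, S, n) {
  if (S < 1) return(NA_real_)
  co <- tajimaCoefficients(n)
  (piTotal - S / co$a1) / sqrt(co$e1 * S + co$e2 * S * (S - 1))
}

# Fu & Li (1993) D* and F* without outgroup, with the Simonsen, Churchill
# & Aquadro (1995) corrected variance constants (the 1993 paper's printed
# constants contain typos; the corrected forms below are the ones standard
# implementations agree on).
fuLiCoefficients <- function(n) {
  a <- harmonicA1(n)          # a_n
  b <- harmonicA2(n)          # b_n
  a1 <- a + 1 / n             # a_{n+1}
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (3 / 2 - (2 * a1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
           2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           (2 * (n - 1) * a) / n^2 - 8 * b / n) / (a^2 + b)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           2 * (n + 1) / (n - 1)^2 * (a1 - 2 * n / (n + 1))) / a - vF
  list(a = a, b = b, uD = uD, vD = vD, uF = uF, vF = vF)
}

fuLiFromStats <- function(eta, etaS, piTotal, n) {
  if (eta < 1) return(list(dstar = NA_real_, fstar = NA_real_))
  co <- fuLiCoefficients(n)
  dstar <- (n / (n - 1) * eta - co$a * etaS) /
    sqrt(co$uD * eta + co$vD * eta^2)
  fstar <- (piTotal - (n - 1) / n * etaS) /
    sqrt(co$uF * eta + co$vF * eta^2)
  list(dstar = dstar, fstar = fstar)
}

#' Tajima's D
#'
#' D contrasts the mean pairwise difference count with the Watterson
#' expectation S/a1, normalized with the Tajima (1989) coefficients.
#' Negative values indicate an excess of rare variants (expansion or
#' sweep), positive values an excess of intermediate-frequency variants.
#'
#' @param aln A [MitoAlignment] with n >= 4.
#' @return D, or NA (with attribute `"undefined"`) when S = 0.
#' @export
tajimasD <- function(aln) {
  n <- nSequences(aln)
  if (n < 4L) stopDegenerate("Tajima's D needs n >= 4")
  ss <- siteSummary(aln)
  nd <- nucleotideDiversity(aln)
  tajimaDFromStats(nd$piTotal, ss$S, n)
}

#' Fu and Li's D* and F* (without outgroup)
#'
#' Contrast total mutations (eta) and singleton mutations (eta_s) — D* —
#' or mean pairwise differences and singletons — F* — using the corrected
#' variance constants (see source). A singleton is a variant whose minority
#' lineage is a single sequence.
#'
#' @param aln A [MitoAlignment] with n >= 4.
#' @return List with `dstar`, `fstar` (NA when eta = 0), plus `eta`,
#'   `etaS`.
#' @export
fuLiTests <- function(aln) {
  n <- nSequences(aln)
  if (n < 4L) stopDegenerate("Fu & Li's tests need n >= 4")
  ss <- siteSummary(aln)
  nd <- nucleotideDiversity(aln)
  fl <- fuLiFromStats(ss$eta, ss$etaS, nd$piTotal, n)
  c(fl, list(eta = ss$eta, etaS = ss$etaS))
}

#' Neutrality statistics with coalescent-simulation p-values
#'
#' Bundles Tajima's D and Fu & Li's D*/F* for one group with two-tailed
#' p-values from [neutralityPvalue()].
#'
#' @param aln A [MitoAlignment] with n >= 4.
#' @param nSims Null simulations per statistic (default 10000).
#' @param seed Integer seed.
#' @return One-row data.frame with the statistics and their p-values.
#' @export
neutralityStats <- function(aln, nSims = 10000L, seed = 1L) {
  n <- nSequences(aln)
  ss <- siteSummary(aln)
  nd <- nucleotideDiversity(aln)
  D <- tajimaDFromStats(nd$piTotal, ss$S, n)
  fl <- fuLiFromStats(ss$eta, ss$etaS, nd$piTotal, n)
  null <- simulateNullStats(n, ss$S, nSims, seed)
  data.frame(n = n, S = ss$S, eta = ss$eta, eta_s = ss$etaS,
             tajima_d = D,
             p_tajima_d = twoTailedP(D, null$D),
             fu_li_dstar = fl$dstar,
             p_fu_li_dstar = twoTailedP(fl$dstar, null$dstar),
             fu_li_fstar = fl$fstar,
             p_fu_li_fstar = twoTailedP(fl$fstar, null$fstar))
}

# simulate the joint null distribution of (D, D*, F*) for fixed n and S
simulateNullStats <- function(n, S, nSims, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- dstar <- fstar <- numeric(nSims)
  for (i in seq_len(nSims)) {
    g <- simulateGenealogy(n)
    mc <- mutationCarrierCounts(g, fixedS = S)
    st <- sfsStatsFromCounts(mc$counts, n)
    D[i] <- tajimaDFromStats(st$piTotal, st$S, n)
    fl <- fuLiFromStats(st$eta, st$etaS, st$piTotal, n)
    dstar[i] <- fl$dstar; fstar[i] <- fl$fstar
  }
  list(D = D, dstar = dstar, fstar = fstar)
}

twoTailedP <- function(obs, null) {
  if (is.na(obs)) return(NA_real_)
  null <- null[!is.na(null)]
  m <- length(null)
  pLow <- (1 + sum(null <= obs)) / (m + 1)
  pHigh <- (1 + sum(null >= obs)) / (m + 1)
  min(1, 2 * min(pLow, pHigh))
}

#' Coalescent-simulation p-value for an SFS neutrality statistic
#'
#' Simulates constant-size coalescent samples of size `n` conditioned on
#' the observed number of segregating sites (fixed-S mutation placement,
#' the convention of the simulation tests it reproduces), recomputes the
#' statistic on each replicate, and returns the two-tailed p-value
#' 2 * min(P(stat <= obs), P(stat >= obs)), capped at 1.
#'
#' @param statName `"tajima_d"`, `"fu_li_dstar"` or `"fu_li_fstar"`.
#' @param observed Observed value of the statistic.
#' @param n Sample size of the data.
#' @param S Observed segregating sites.
#' @param nSims Number of null simulations (default 10000).
#' @param seed Integer seed.
#' @return p-value in (0, 1].
#' @export
neutralityPvalue <- function(statName = c("tajima_d", "fu_li_dstar",
                                          "fu_li_fstar"),
                             observed, n, S, nSims = 10000L, seed = 1L) {
  statName <- match.arg(statName)
  null <- simulateNullStats(n, S, nSims, seed)
  pick <- switch(statName, tajima_d = null$D, fu_li_dstar = null$dstar,
                 fu_li_fstar = null$fstar)
  twoTailedP(observed, pick)
}

#' Expected mismatch distribution
#'
#' Probability that a random sequence pair differs at k sites,
#' k = 0..maxK. Under the constant-size model this is the geometric
#' F(k) = theta^k / (theta+1)^(k+1) (theta taken from `theta0`). Under the
#' sudden-expansion model the population had diversity `theta0` until
#' `tau` mutational units ago and `theta1` since; the transient
#' distribution is the equilibrium law at theta1 plus an exponentially
#' damped convolution term (the two-epoch pair-coalescent closed form).
#'
#' @param model `"constant"` or `"sudden_expansion"`.
#' @param theta0 Diversity before the change (the constant model's theta).
#' @param theta1 Diversity after the change.
#' @param tau Change date in mutational units.
#' @param maxK Largest difference count to evaluate.
#' @return Numeric vector of length maxK+1 (index 1 = zero differences)
#'   with attribute `"tailMass"` = 1 - sum.
#' @export
mismatchExpected <- function(model = c("constant", "sudden_expansion"),
                             theta0, theta1 = NULL, tau = NULL,
                             maxK = 50L) {
  model <- match.arg(model)
  if (maxK < 1L) stopInput("maxK must be >= 1")
  geomF <- function(theta, k) {
    if (theta <= 0) return(as.numeric(k == 0L))
    exp(k * log(theta) - (k + 1) * log(theta + 1))
  }
  k <- 0:maxK
  if (model == "constant") {
    if (!is.finite(theta0) || theta0 < 0)
      stopInput("theta must be finite and >= 0")
    out <- geomF(theta0, k)
  } else {
    if (any(!is.finite(c(theta0, theta1, tau))) ||
        any(c(theta0, theta1, tau) < 0))
      stopInput("parameters must be finite and >= 0")
    f1 <- geomF(theta1, k)
    f0 <- geomF(theta0, k)
    if (theta1 <= 0) {
      # no present-day diversity: all pairs coalesce immediately
      out <- as.numeric(k == 0L)
    } else {
      damp <- -tau * (theta1 + 1) / theta1
      # log(tau^j / j!) terms; tau = 0 collapses onto f0
      if (tau == 0) {
        out <- f0
      } else {
        a <- exp(damp + k * log(tau) - lgamma(k + 1))
        diff0 <- f0 - f1
        # polynomial product a * diff0 truncated at degree maxK
        conv <- stats::convolve(a, rev(diff0), type = "open")
        out <- f1 + conv[seq_len(maxK + 1L)]
      }
    }
  }
  out <- pmax(out, 0)
  attr(out, "tailMass") <- max(0, 1 - sum(out))
  out
}

#' Observed mismatch histogram
#'
#' Counts pairwise differences over usable columns (complete deletion)
#' for all C(n,2) sequence pairs.
#'
#' @param aln A [MitoAlignment] with n >= 2.
#' @return Integer vector; element k+1 is the number of pairs differing at
#'   k sites.
#' @export
mismatchHistogram <- function(aln) {
  codes <- baseCodeMatrix(aln)
  n <- nrow(codes)
  if (n < 2L) stopDegenerate("mismatch histogram needs n >= 2")
  keep <- usableColumns(codes)
  sub <- codes[, keep, drop = FALSE]
  diffs <- integer(choose(n, 2))
  idx <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    idx <- idx + 1L
    diffs[idx] <- sum(sub[i, ] != sub[j, ])
  }
  tabulate(diffs + 1L, nbins = max(diffs) + 1L)
}

# differences histogram straight from simulated derived-allele carriers
mismatchFromCarriers <- function(carriers, n) {
  d <- matrix(0L, n, n)
  for (cset in carriers) {
    d[cset, -cset] <- d[cset, -cset] + 1L
  }
  d <- d + t(d)
  diffs <- d[upper.tri(d)]
  tabulate(diffs + 1L, nbins = max(diffs, 0L) + 1L)
}

mismatchSSD <- function(obsFreq, theta0, theta1, tau) {
  K <- length(obsFreq) - 1L
  expd <- mismatchExpected("sudden_expansion", theta0, theta1, tau,
                           maxK = K)
  sum((obsFreq - expd)^2)
}

# bounded multi-start least-squares fit of (theta0, theta1, tau)
fitMismatchCore <- function(obs, starts, constrained = FALSE) {
  freq <- obs / sum(obs)
  obj <- function(p) {
    if (constrained && p[2] < p[1]) return(1e6 + (p[1] - p[2]))
    mismatchSSD(freq, p[1], p[2], p[3])
  }
  best <- NULL
  anyConv <- FALSE
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::nlminb(starts[s, ], obj, lower = c(1e-6, 1e-6, 0),
                    upper = c(1e4, 1e5, 1e3)),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv <- fit$convergence == 0
    anyConv <- anyConv || conv
    # ties broken by lowest SSD then lowest tau
    if (is.null(best) || fit$objective < best$objective - 1e-12 ||
        (abs(fit$objective - best$objective) <= 1e-12 &&
         fit$par[3] < best$par[3]))
      best <- fit
  }
  if (is.null(best))
    stopDegenerate("mismatch fit failed from every starting point")
  list(par = best$par, ssd = best$objective, converged = anyConv)
}

defaultStarts <- function(obs) {
  k <- seq_along(obs) - 1L
  meanDiff <- sum(k * obs) / sum(obs)
  rbind(c(0.1, max(meanDiff, 1), max(meanDiff, 0.5)),
        c(1, 10, 1),
        c(1, 100, 5),
        c(0.1, max(2 * meanDiff, 2), max(meanDiff / 2, 0.25)),
        c(10, 100, 10),
        c(0.01, max(meanDiff, 1), max(2 * meanDiff, 1)),
        c(1, 1000, max(meanDiff, 1)),
        c(0.5, max(meanDiff, 1), 0.05))
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Estimates (theta0, theta1, tau) by bounded nonlinear least squares on
#' the observed mismatch frequencies, using eight deterministic starting
#' points spanning several parameter decades (ties broken by lowest SSD,
#' then lowest tau). The parametric bootstrap resimulates `B` coalescent
#' data sets of the same sample size under the fitted expansion, refits
#' each (warm-started at the point estimate), and reports 95% percentile
#' confidence intervals per parameter plus the goodness-of-fit p-value
#' p_SSD = P(bootstrap SSD >= observed SSD).
#'
#' @param obs Mismatch histogram (index 1 = zero differences), e.g. from
#'   [mismatchHistogram()]; must total C(n,2) for some n >= 3. Non-integer
#'   counts are accepted (e.g. exact model expectations scaled to C(n,2)
#'   pairs).
#' @param B Bootstrap replicates (default 10000; set 0 to skip).
#' @param seed Integer seed for the bootstrap.
#' @param constrained Force theta1 >= theta0 (off by default; both modes
#'   supported).
#' @return A [MismatchFit].
#' @export
fitSuddenExpansion <- function(obs, B = 10000L, seed = 1L,
                               constrained = FALSE) {
  obs <- as.numeric(obs)
  if (any(obs < 0)) stopInput("histogram counts must be >= 0")
  nPairs <- sum(obs)
  n <- round((1 + sqrt(1 + 8 * nPairs)) / 2)
  if (abs(choose(n, 2) - nPairs) > 1e-6 || n < 3L)
    stopInput("histogram total %d is not C(n,2) for any n >= 3", nPairs)
  if (length(obs) == 1L) {
    # monomorphic data: expansion date collapses to the tau = 0 boundary
    return(methods::new("MismatchFit", observed = obs,
                        model = "sudden_expansion", theta0 = 0, theta1 = 0,
                        tau = 0, ssd = 0,
                        ci = matrix(numeric(), 0, 2), pSsd = NA_real_,
                        B = 0L, seed = as.integer(seed), nSeq = as.integer(n),
                        converged = TRUE))
  }
  fit <- fitMismatchCore(obs, defaultStarts(obs), constrained)
  if (!fit$converged)
    warning("mismatch optimizer did not converge from any start")
  ci <- matrix(numeric(), 0L, 2L)
  pSsd <- NA_real_
  B <- as.integer(B)
  if (B > 0L) {
    set.seed(seed)
    model <- demographyModel("sudden_expansion", fit$par[1], fit$par[2],
                             fit$par[3])
    boot <- matrix(NA_real_, nrow = B, ncol = 4L)
    for (b in seq_len(B)) {
      g <- simulateGenealogy(n, model)
      mc <- mutationCarrierCounts(g, theta = fit$par[2], carriers = TRUE)
      h <- mismatchFromCarriers(mc$carriers, n)
      starts <- rbind(fit$par, defaultStarts(h)[2L, ])
      bf <- fitMismatchCore(h, starts, constrained)
      boot[b, ] <- c(bf$par, bf$ssd)
    }
    qs <- apply(boot[, 1:3, drop = FALSE], 2L, stats::quantile,
                probs = c(0.025, 0.975), na.rm = TRUE)
    ci <- t(qs)
    rownames(ci) <- c("theta0", "theta1", "tau")
    colnames(ci) <- c("lower", "upper")
    pSsd <- mean(boot[, 4L] >= fit$ssd, na.rm = TRUE)
  }
  methods::new("MismatchFit", observed = obs, model = "sudden_expansion",
               theta0 = fit$par[1], theta1 = fit$par[2], tau = fit$par[3],
               ssd = fit$ssd, ci = ci, pSsd = pSsd, B = B,
               seed = as.integer(seed), nSeq = as.integer(n),
               converged = fit$converged)
}

#' Convert tau to calendar time, and theta to effective size
#'
#' tau = 2 * mu_seq * t with mu_seq the mutation rate per sequence per
#' generation (mu_seq = rate * L * generationYears for a rate given per
#' site per year). For a maternally inherited, effectively haploid
#' mitochondrial genome, Ne = theta_total / (2 * mu_seq).
#'
#' @param tau Expansion date in mutational units.
#' @param ratePerSitePerYear Substitution rate per site per year.
#' @param L Sequence length (bp).
#' @param generationYears Generation time in years.
#' @return `tauToTime()`: list with `tGenerations`, `tYears`;
#'   `thetaToNe()`: effective (female) population size.
#' @export
tauToTime <- function(tau, ratePerSitePerYear, L, generationYears) {
  if (any(c(ratePerSitePerYear, L, generationYears) <= 0) || tau < 0)
    stopInput("rates, lengths and times must be positive (tau >= 0)")
  muSeq <- ratePerSitePerYear * L * generationYears
  tGen <- tau / (2 * muSeq)
  list(tGenerations = tGen, tYears = tGen * generationYears)
}

#' @rdname tauToTime
#' @param thetaTotal Diversity per sequence (not per site).
#' @param muSeqPerGen Mutation rate per sequence per generation.
#' @export
thetaToNe <- function(thetaTotal, muSeqPerGen) {
  if (muSeqPerGen <= 0 || thetaTotal < 0)
    stopInput("rates must be positive and theta >= 0")
  thetaTotal / (2 * muSeqPerGen)
}
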