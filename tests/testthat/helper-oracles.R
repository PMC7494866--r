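# Independent oracle implementations, written from the definitions by
# explicit enumeration. They deliberately share no code with the package
# internals: everything is plain loops over a character matrix.

oracleCharMatrix <- function(aln) {
  do.call(rbind, strsplit(as.character(alignmentSeqs(aln)), ""))
}

# brute-force diversity statistics by direct column/pair scans
oracleDiversity <- function(aln) {
  m <- oracleCharMatrix(aln)
  n <- nrow(m)
  usable <- logical(ncol(m))
  for (j in seq_len(ncol(m)))
    usable[j] <- all(m[, j] %in% c("A", "C", "G", "T"))
  mm <- m[, usable, drop = FALSE]
  L <- ncol(mm)
  S <- 0L; singl <- 0L; shared <- 0L
  for (j in seq_len(L)) {
    states <- unique(mm[, j])
    if (length(states) < 2L) next
    S <- S + 1L
    cs <- sapply(states, function(s) sum(mm[, j] == s))
    major <- states[which.max(cs)]
    minorCounts <- cs[states != major]
    if (all(minorCounts == 1L)) singl <- singl + 1L else shared <- shared + 1L
  }
  # haplotypes over usable columns
  haps <- apply(mm, 1L, paste, collapse = "")
  H <- length(unique(haps))
  p <- as.numeric(table(haps)) / n
  Hd <- n / (n - 1) * (1 - sum(p^2))
  # pi by explicit pair loop
  tot <- 0
  for (i in seq_len(n - 1L)) for (k in (i + 1L):n)
    tot <- tot + sum(mm[i, ] != mm[k, ])
  piTotal <- tot / (n * (n - 1) / 2)
  a1 <- sum(1 / seq_len(n - 1L))
  list(S = S, singletons = singl, shared = shared, usable = L, H = H,
       Hd = Hd, piTotal = piTotal, piPerSite = piTotal / L,
       thetaW = S / (a1 * L))
}

# Tajima (1989) D, transcribed coefficient by coefficient
oracleTajimaD <- function(piTotal, S, n) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1^2)
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (piTotal - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Fu & Li (1993) D* / F* without outgroup, corrected constants
# (Simonsen, Churchill & Aquadro 1995), transcribed independently
oracleFuLi <- function(eta, etaS, piTotal, n) {
  an <- sum(1 / (1:(n - 1)))
  bn <- sum(1 / (1:(n - 1))^2)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / ((n - 1)^2)) / (an^2 + bn)
  uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
  Dstar <- ((n / (n - 1)) * eta - an * etaS) / sqrt(uD * eta + vD * eta^2)
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           (2 * (n - 1) * an) / n^2 - (8 * bn) / n) / (an^2 + bn)
  uF <- ((n / (n - 1)) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           (2 * (n + 1)) / ((n - 1)^2) * (an1 - 2 * n / (n + 1))) / an - vF
  Fstar <- (piTotal - ((n - 1) / n) * etaS) / sqrt(uF * eta + vF * eta^2)
  list(dstar = Dstar, fstar = Fstar)
}

# eta / etaS / piTotal by direct scans (multi-allelic aware)
oracleEta <- function(aln) {
  m <- oracleCharMatrix(aln)
  n <- nrow(m)
  eta <- 0L; etaS <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (!all(col %in% c("A", "C", "G", "T"))) next
    cs <- table(col)
    if (length(cs) < 2L) next
    eta <- eta + length(cs) - 1L
    if (n == 2L) etaS <- etaS + 1L
    else etaS <- etaS + sum(cs == 1L)
  }
  list(eta = eta, etaS = etaS)
}

# Nei-Gojobori site fractions by exhaustive neighbor enumeration against
# the Biostrings code table
oracleCodonSites <- function(codon, code = Biostrings::getGeneticCode("2")) {
  sp <- strsplit(codon, "")[[1]]
  syn <- 0; nonsyn <- 0; stopFrac <- 0
  for (p in 1:3) for (b in c("A", "C", "G", "T")) {
    if (b == sp[p]) next
    q <- sp; q[p] <- b
    aaFrom <- code[[codon]]; aaTo <- code[[paste(q, collapse = "")]]
    if (aaTo == "*" && aaFrom != "*") stopFrac <- stopFrac + 1 / 3
    else if (aaTo == aaFrom) syn <- syn + 1 / 3
    else nonsyn <- nonsyn + 1 / 3
  }
  c(syn = syn, nonsyn = nonsyn, stop = stopFrac)
}
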