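# Fixture builders shared across test files.

makeAln <- function(seqs, ids = NULL) porpopgen:::newAlignment(seqs, ids)

# random alignment over ACGT with optional gap/N noise
randomAln <- function(n, L, pGap = 0) {
  alphabet <- c("A", "C", "G", "T")
  m <- matrix(sample(alphabet, n * L, replace = TRUE), nrow = n)
  if (pGap > 0) {
    noise <- sample(c("-", "N"), n * L, replace = TRUE)
    sel <- stats::runif(n * L) < pGap
    m[sel] <- noise[sel]
  }
  makeAln(apply(m, 1L, paste, collapse = ""))
}

# tiny two-gene annotation used by partition tests
twoGeneAnnotation <- function() {
  geneAnnotation(name = c("A", "B"), start = c(1L, 7L), end = c(9L, 12L),
                 strand = c("+", "-"), klass = c("CDS", "CDS"))
}

# codon alignment built directly from a matrix of codon strings
codonAlnFromMatrix <- function(m, ids = paste0("s", seq_len(nrow(m))),
                               gene = "g1") {
  genes <- list(m)
  names(genes) <- gene
  methods::new("CodonAlignment", genes = genes, sampleIds = ids,
               geneticCode = "2", dropped = stats::setNames(0L, gene))
}

# simulate a neutral ingroup/outgroup codon-alignment pair: mutations fall
# uniformly over codon positions with a uniformly chosen alternative base,
# identically for polymorphism and divergence
simulateMKPair <- function(nIn, nCodons, thetaIn, divMean) {
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "AGA", "AGG")
  anc <- character(nCodons)
  for (i in seq_len(nCodons)) {
    repeat {
      cod <- paste(sample(bases, 3L, replace = TRUE), collapse = "")
      if (!(cod %in% stops)) break
    }
    anc[i] <- cod
  }
  # one infinite-sites mutation at flat nucleotide position p, applied to
  # the rows in `rows` of codon matrix `m` (cumulative, so several
  # mutations can hit the same codon consistently)
  applyMut <- function(m, rows, p) {
    ci <- (p - 1L) %/% 3L + 1L
    pos <- (p - 1L) %% 3L + 1L
    ancBase <- substr(anc[ci], pos, pos)
    b <- sample(setdiff(bases, ancBase), 1L)
    x <- m[rows, ci]
    substr(x, pos, pos) <- b
    m[rows, ci] <- x
    m
  }
  ing <- matrix(rep(anc, each = nIn), nrow = nIn)
  g <- simulateGenealogy(nIn)
  mut <- porpopgen:::mutationCarrierCounts(g, theta = thetaIn,
                                           carriers = TRUE)
  posPool <- sample.int(3L * nCodons)
  k <- 0L
  for (carr in mut$carriers) {
    k <- k + 1L
    if (k > length(posPool)) break
    ing <- applyMut(ing, carr, posPool[k])
  }
  outg <- matrix(anc, nrow = 1L)
  nDiv <- stats::rpois(1L, divMean)
  for (d in seq_len(nDiv)) {
    k <- k + 1L
    if (k > length(posPool)) break
    outg <- applyMut(outg, 1L, posPool[k])
  }
  list(ingroup = codonAlnFromMatrix(ing),
       outgroup = codonAlnFromMatrix(outg, ids = "out1"))
}
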