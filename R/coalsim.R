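# Kingman coalescent simulator with constant-size and sudden-expansion
# demographies, infinite-sites mutation, and a synthetic annotated
# mitogenome generator. All times are in coalescent units of the
# present-day population (pairwise coalescence rate 1); mutations are laid
# down at rate theta/2 per branch per unit time so that, for a pair,
# E[differences] = theta and E[S] = theta * a1 for a sample of n.

#' Demographic model for the coalescent simulator
#'
#' `constant` keeps the scaled diversity at `theta1` forever;
#' `sudden_expansion` has present-day diversity `theta1` back to `tau`
#' mutational units ago (tau = 2*mu*t) and ancestral diversity `theta0`
#' before that. Internally the change point is converted once to
#' coalescent units via theta1 (t_change = tau / theta1).
#'
#' @param kind `"constant"` or `"sudden_expansion"`.
#' @param theta0 Ancestral scaled diversity (ignored for `constant`).
#' @param theta1 Present-day scaled diversity (per sequence).
#' @param tau Change date in mutational units (ignored for `constant`).
#' @return A `demographyModel` list.
#' @export
demographyModel <- function(kind = c("constant", "sudden_expansion"),
                            theta0 = 0, theta1 = 1, tau = 0) {
  kind <- match.arg(kind)
  if (any(c(theta0, theta1, tau) < 0))
    stopInput("demography parameters must be >= 0")
  structure(list(kind = kind, theta0 = theta0, theta1 = theta1, tau = tau),
            class = "demographyModel")
}

#' Simulate a coalescent genealogy
#'
#' Standard Kingman coalescent: with k lineages the waiting time to the
#' next coalescence is exponential with rate C(k,2) scaled by the inverse
#' relative population size, and the pair to merge is uniform. Under
#' `sudden_expansion` the relative size switches from 1 to theta0/theta1
#' at tau/theta1 coalescent units in the past.
#'
#' @param n Number of tips (>= 2).
#' @param model A [demographyModel()].
#' @param seed Optional integer seed (set once; omit inside loops that
#'   manage their own RNG state).
#' @return A [Genealogy].
#' @export
simulateGenealogy <- function(n, model = demographyModel("constant"),
                              seed = NULL) {
  if (n < 2L) stopInput("simulateGenealogy needs n >= 2")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  nNodes <- 2L * n - 1L
  parent <- integer(nNodes)
  nodeTime <- numeric(nNodes)
  active <- seq_len(n)
  t <- 0
  nextNode <- n + 1L
  # epoch boundary in coalescent units; Inf for constant size
  if (model$kind == "sudden_expansion" && model$theta1 > 0) {
    tChange <- model$tau / model$theta1
    relAncestral <- if (model$theta1 > 0) model$theta0 / model$theta1 else 1
  } else {
    tChange <- Inf
    relAncestral <- 1
  }
  for (k in seq(n, 2L)) {
    rate <- choose(k, 2)
    if (t < tChange) {
      w <- stats::rexp(1L, rate)
      if (t + w > tChange) {
        # residual waiting carries over into the ancestral epoch, rescaled
        resid <- (t + w) - tChange
        if (relAncestral <= 0) {
          # ancestral size ~0: immediate coalescence at the boundary
          w <- tChange - t
        } else {
          w <- (tChange - t) + resid * relAncestral
        }
      }
    } else {
      if (relAncestral <= 0) w <- 0
      else w <- stats::rexp(1L, rate / relAncestral)
    }
    t <- t + w
    pick <- sample.int(k, 2L)
    a <- active[pick[1L]]; b <- active[pick[2L]]
    parent[a] <- nextNode
    parent[b] <- nextNode
    nodeTime[nextNode] <- t
    active <- c(active[-pick], nextNode)
    nextNode <- nextNode + 1L
  }
  methods::new("Genealogy", n = n, parent = parent, nodeTime = nodeTime)
}

# tips below each node, as a list over all nodes
tipsBelow <- function(g) {
  nNodes <- 2L * g@n - 1L
  below <- vector("list", nNodes)
  for (i in seq_len(g@n)) below[[i]] <- i
  # children in node order: parents always have larger index
  for (i in seq_len(nNodes - 1L))
    below[[g@parent[i]]] <- c(below[[g@parent[i]]], below[[i]])
  lapply(below, function(x) sort(unique(x[x <= g@n])))
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' Either a Poisson(theta/2 * total branch length) number of mutations
#' (`theta` mode) or exactly `S` mutations (`fixed_S` mode) are placed
#' uniformly at random on the branches; every mutation founds a new
#' biallelic column whose derived state is carried by the tips below its
#' branch.
#'
#' @param g A [Genealogy].
#' @param theta Scaled mutation rate (per sequence); used when `fixedS` is
#'   NULL.
#' @param fixedS Exact number of mutations to place (fixed-S mode used by
#'   the neutrality-test null distributions), or NULL.
#' @param seed Optional integer seed.
#' @return Binary matrix (n tips x mutations); 1 = derived. Zero columns
#'   when no mutation falls.
#' @export
dropMutations <- function(g, theta = NULL, fixedS = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- mutationCarrierCounts(g, theta, fixedS, carriers = TRUE)
  n <- g@n
  mat <- matrix(0L, nrow = n, ncol = length(counts$carriers))
  for (j in seq_along(counts$carriers)) mat[counts$carriers[[j]], j] <- 1L
  rownames(mat) <- paste0("tip", seq_len(n))
  mat
}

# Internal: place mutations and return derived-allele counts (and carrier
# sets when carriers = TRUE). Count-only mode keeps the simulation-based
# null distributions fast.
mutationCarrierCounts <- function(g, theta = NULL, fixedS = NULL,
                                  carriers = FALSE) {
  bl <- branchLengths(g)
  tot <- sum(bl)
  nMut <- if (!is.null(fixedS)) {
    if (fixedS < 0) stopInput("fixedS must be >= 0")
    as.integer(fixedS)
  } else {
    if (is.null(theta) || theta < 0) stopInput("theta must be >= 0")
    stats::rpois(1L, theta / 2 * tot)
  }
  if (nMut == 0L)
    return(list(counts = integer(), carriers = list()))
  branch <- sample.int(length(bl), nMut, replace = TRUE, prob = bl)
  below <- tipsBelow(g)
  cnts <- vapply(branch, function(b) length(below[[b]]), 0L)
  out <- list(counts = cnts)
  if (carriers) out$carriers <- below[branch]
  out
}

# SFS-style statistics from derived-allele counts (infinite sites):
# S, eta (= S), singleton mutations, pi_total.
sfsStatsFromCounts <- function(counts, n) {
  S <- length(counts)
  piTotal <- if (S) sum(2 * counts * (n - counts)) / (n * (n - 1)) else 0
  etaS <- sum(counts == 1L | counts == (n - 1L))
  # without an outgroup a derived count of n-1 is also a single-carrier
  # variant; Fu & Li's starred tests count size-1 *minor* lineages, and the
  # folded convention counts both 1 and n-1 classes
  etaSFolded <- sum(counts == 1L | counts == (n - 1L))
  list(S = S, eta = S, etaS = etaSFolded, piTotal = piTotal)
}

#' Default synthetic mitogenome annotation template
#'
#' A compact annotation emulating the mammalian mitochondrial gene order:
#' 2 rRNAs, 13 protein-coding genes (one, "ND6", on the minus strand and
#' overlapping the 3' end of "ND5" by 17 bp), 22 tRNAs, a replication
#' origin, and a terminal control region, scaled to the requested genome
#' length.
#'
#' @param genomeLength Total genome length in bp (default 16302).
#' @return Annotation `GRanges` (see [geneAnnotation()]).
#' @export
defaultMitoAnnotation <- function(genomeLength = 16302L) {
  cdsLen <- c(ND1 = 957, ND2 = 1044, COX1 = 1545, COX2 = 684, ATP8 = 204,
              ATP6 = 681, COX3 = 784, ND3 = 345, ND4L = 297, ND4 = 1377,
              ND5 = 1821, ND6 = 528, CYTB = 1140)
  cdsLen <- cdsLen - cdsLen %% 3L  # keep frames whole
  feats <- list()
  pos <- 1L
  addFeat <- function(name, len, strand = "+", klass = "CDS", overlap = 0L) {
    start <- pos - overlap
    feats[[name]] <<- data.frame(name = name, start = start,
                                 end = start + len - 1L, strand = strand,
                                 klass = klass)
    pos <<- start + len
  }
  addFeat("tRNA-Phe", 70L, klass = "tRNA")
  addFeat("rRNA-12S", 960L, klass = "rRNA")
  addFeat("tRNA-Val", 70L, klass = "tRNA")
  addFeat("rRNA-16S", 1560L, klass = "rRNA")
  addFeat("tRNA-Leu", 72L, klass = "tRNA")
  tRNAafter <- c(ND1 = 2L, ND2 = 3L, COX1 = 2L, COX2 = 1L, ATP8 = 0L,
                 ATP6 = 0L, COX3 = 1L, ND3 = 1L, ND4L = 0L, ND4 = 3L,
                 ND5 = 0L, ND6 = 1L, CYTB = 2L)
  tCount <- 5L
  for (gene in names(cdsLen)) {
    if (gene == "ND6") {
      # minus strand, 17-bp overlap with the end of ND5
      addFeat(gene, cdsLen[[gene]], strand = "-", overlap = 17L)
    } else {
      addFeat(gene, cdsLen[[gene]])
    }
    for (i in seq_len(tRNAafter[[gene]])) {
      tCount <- tCount + 1L
      addFeat(sprintf("tRNA-%02d", tCount), 70L, klass = "tRNA")
    }
  }
  addFeat("OriL", 30L, klass = "origin")
  df <- do.call(rbind, feats)
  if (pos > genomeLength - 100L)
    stopInput("genomeLength %d too short for the default template",
              genomeLength)
  df <- rbind(df, data.frame(name = "D-loop", start = pos,
                             end = genomeLength, strand = "+",
                             klass = "noncoding"))
  geneAnnotation(df$name, df$start, df$end, df$strand, df$klass)
}

# --- ancestral genome construction ------------------------------------

STOP_CODONS_MT <- c("TAA", "TAG", "AGA", "AGG")

randomNonStopCodon <- function(k = 1L) {
  bases <- c("A", "C", "G", "T")
  out <- character(k)
  for (i in seq_len(k)) {
    repeat {
      cod <- paste(sample(bases, 3L, replace = TRUE), collapse = "")
      if (!(cod %in% STOP_CODONS_MT)) break
    }
    out[i] <- cod
  }
  out
}

# Fill a genome with random bases, then overwrite CDS regions with stop-free
# reading frames (minus-strand genes framed on the reverse complement).
# Overlapping spans are resolved by regenerating the earlier gene's
# overlapping codons until both frames are stop-free (bounded retries).
buildAncestralGenome <- function(ann, genomeLength) {
  bases <- c("A", "C", "G", "T")
  genome <- sample(bases, genomeLength, replace = TRUE)
  st <- GenomicRanges::start(ann); en <- GenomicRanges::end(ann)
  kl <- S4Vectors::mcols(ann)$klass
  strd <- as.character(GenomicRanges::strand(ann))
  cdsIdx <- which(kl == "CDS")
  writeGene <- function(genome, i) {
    len <- en[i] - st[i] + 1L
    codons <- randomNonStopCodon(len %/% 3L)
    seq <- strsplit(paste(codons, collapse = ""), "")[[1]]
    if (len %% 3L) seq <- c(seq, sample(bases, len %% 3L, replace = TRUE))
    if (strd[i] == "-") seq <- reverseComplementChars(seq)
    genome[st[i]:en[i]] <- seq
    genome
  }
  for (i in cdsIdx) genome <- writeGene(genome, i)
  # repair frames broken by overlap: later gene wins, earlier rechecked
  hasStop <- function(genome, i) {
    seq <- genome[st[i]:en[i]]
    if (strd[i] == "-") seq <- reverseComplementChars(seq)
    len <- length(seq) - length(seq) %% 3L
    cods <- apply(matrix(seq[seq_len(len)], nrow = 3L), 2L, paste,
                  collapse = "")
    any(cods %in% STOP_CODONS_MT)
  }
  for (attempt in seq_len(200L)) {
    bad <- cdsIdx[vapply(cdsIdx, function(i) hasStop(genome, i), TRUE)]
    if (length(bad) == 0L) break
    for (i in bad) genome <- writeGene(genome, i)
  }
  if (length(bad <- cdsIdx[vapply(cdsIdx, function(i) hasStop(genome, i),
                                  TRUE)]))
    warning("ancestral genome retains internal stop codon(s) in: ",
            paste(S4Vectors::mcols(ann)$name[bad], collapse = ", "))
  genome
}

# Classify a one-step change at genome position pos (ancestral genome as a
# char vector) as synonymous/nonsynonymous given the containing CDS.
# Returns the candidate derived bases of each class.
cdsChangeClasses <- function(genome, pos, gene, code) {
  st <- gene$start; en <- gene$end
  if (gene$strand == "-") {
    off <- en - pos                       # 0-based offset in sense frame
  } else {
    off <- pos - st
  }
  codonIdx <- off %/% 3L
  posInCodon <- off %% 3L + 1L
  span <- if (gene$strand == "-") (en - 3L * codonIdx):(en - 3L * codonIdx - 2L)
          else (st + 3L * codonIdx):(st + 3L * codonIdx + 2L)
  codon <- genome[span]
  if (gene$strand == "-") codon <- chartr(COMPLEMENT_FROM, COMPLEMENT_TO,
                                          codon)
  codonStr <- paste(codon, collapse = "")
  aa <- code[[codonStr]]
  senseBase <- codon[posInCodon]
  alt <- setdiff(c("A", "C", "G", "T"), senseBase)
  syn <- character(); nonsyn <- character()
  for (b in alt) {
    cod2 <- codon; cod2[posInCodon] <- b
    aa2 <- code[[paste(cod2, collapse = "")]]
    genomeBase <- if (gene$strand == "-")
      chartr(COMPLEMENT_FROM, COMPLEMENT_TO, b) else b
    if (identical(aa2, "*")) next   # changes creating stops are skipped
    if (identical(aa2, aa)) syn <- c(syn, genomeBase)
    else nonsyn <- c(nonsyn, genomeBase)
  }
  list(syn = syn, nonsyn = nonsyn)
}

#' Generate an annotated synthetic mitogenome data set
#'
#' Builds a random ancestral genome with stop-free CDS reading frames under
#' the vertebrate mitochondrial code, then simulates one coalescent
#' genealogy per group and maps infinite-sites mutations onto distinct
#' genome positions. Mutations landing in a CDS are forced to be
#' nonsynonymous with probability `cdsNonsynFraction` (and synonymous
#' otherwise) by rejection-sampling target positions; an optional number of
#' extra divergence mutations separates each group's ancestor from the
#' shared root genome so that between-group tests (e.g. McDonald-Kreitman)
#' see fixed differences.
#'
#' @param groups data.frame with columns `species`, `lineage`, `n` and
#'   optionally `kind`, `theta0`, `theta1`, `tau` (see [demographyModel()];
#'   defaults: constant, theta1 = 5) and `divergence` (expected mutations
#'   from the root to the group ancestor; default 0).
#' @param genomeLength Genome length in bp.
#' @param ann Annotation template (default [defaultMitoAnnotation()]).
#' @param cdsNonsynFraction Fraction of CDS mutations that are
#'   nonsynonymous (default 0.3).
#' @param seed Integer seed; identical configuration and seed give
#'   byte-identical output files.
#' @param dir Output directory; created if needed. Set NULL to skip writing.
#' @return Invisibly, a list with the `alignment` ([MitoAlignment]), `ann`,
#'   `lineages` table, per-group mutation bookkeeping (`mutations`), and the
#'   output `paths` (when written).
#' @export
synthMitogenomeSet <- function(groups, genomeLength = 16302L,
                               ann = defaultMitoAnnotation(genomeLength),
                               cdsNonsynFraction = 0.3, seed = 1L,
                               dir = NULL) {
  if (cdsNonsynFraction < 0 || cdsNonsynFraction > 1)
    stopInput("cdsNonsynFraction must be in [0, 1]")
  if (max(GenomicRanges::end(ann)) > genomeLength)
    stopInput("annotation extends past genomeLength")
  set.seed(seed)
  code <- Biostrings::getGeneticCode("2")
  genome <- buildAncestralGenome(ann, genomeLength)

  st <- GenomicRanges::start(ann); en <- GenomicRanges::end(ann)
  kl <- S4Vectors::mcols(ann)$klass
  nm <- S4Vectors::mcols(ann)$name
  strd <- as.character(GenomicRanges::strand(ann))
  cdsIdx <- which(kl == "CDS")
  inCDS <- rep(FALSE, genomeLength)
  firstGene <- integer(genomeLength)
  for (i in rev(cdsIdx)) {           # earlier genes take precedence
    inCDS[st[i]:en[i]] <- TRUE
    firstGene[st[i]:en[i]] <- i
  }
  cdsPositions <- which(inCDS)
  nonCdsPositions <- which(!inCDS)

  used <- rep(FALSE, genomeLength)
  fallbackCount <- 0L

  # pick a position + derived base for one mutation
  pickMutation <- function() {
    pos <- sample.int(genomeLength, 1L)
    while (used[pos]) pos <- sample.int(genomeLength, 1L)
    if (!inCDS[pos]) {
      derived <- sample(setdiff(c("A", "C", "G", "T"), genome[pos]), 1L)
      return(list(pos = pos, derived = derived, klass = "noncds",
                  effect = NA_character_))
    }
    wantNonsyn <- stats::runif(1L) < cdsNonsynFraction
    for (try in seq_len(50L)) {
      gi <- firstGene[pos]
      gene <- list(start = st[gi], end = en[gi], strand = strd[gi])
      cls <- cdsChangeClasses(genome, pos, gene, code)
      cand <- if (wantNonsyn) cls$nonsyn else cls$syn
      if (length(cand) > 0L)
        return(list(pos = pos, derived = sample(cand, 1L), klass = "cds",
                    effect = if (wantNonsyn) "nonsyn" else "syn"))
      repeat {
        pos <- cdsPositions[sample.int(length(cdsPositions), 1L)]
        if (!used[pos]) break
      }
    }
    fallbackCount <<- fallbackCount + 1L
    cand <- c(cls$syn, cls$nonsyn)
    if (length(cand) == 0L)
      cand <- setdiff(c("A", "C", "G", "T"), genome[pos])
    list(pos = pos, derived = sample(cand, 1L), klass = "cds",
         effect = "fallback")
  }

  defaults <- list(kind = "constant", theta0 = 0, theta1 = 5, tau = 0,
                   divergence = 0)
  for (col in names(defaults))
    if (is.null(groups[[col]])) groups[[col]] <- defaults[[col]]

  seqs <- character(0)
  lineageRows <- list()
  mutLog <- list()
  for (gIdx in seq_len(nrow(groups))) {
    grp <- groups[gIdx, ]
    model <- demographyModel(grp$kind, grp$theta0, grp$theta1, grp$tau)
    # group ancestor: root genome + divergence mutations
    anc <- genome
    nDiv <- stats::rpois(1L, grp$divergence)
    divLog <- character(nDiv)
    for (d in seq_len(nDiv)) {
      mu <- pickMutation()
      used[mu$pos] <- TRUE
      anc[mu$pos] <- mu$derived
      divLog[d] <- mu$effect
    }
    # single-sample groups (e.g. a lone outgroup specimen) carry only the
    # divergence mutations, no within-group polymorphism
    mut <- if (grp$n >= 2L) {
      gen <- simulateGenealogy(grp$n, model)
      mutationCarrierCounts(gen, theta = grp$theta1, carriers = TRUE)
    } else list(counts = integer(), carriers = list())
    tipSeqs <- matrix(rep(anc, grp$n), nrow = grp$n, byrow = TRUE)
    polyLog <- character(length(mut$carriers))
    for (j in seq_along(mut$carriers)) {
      mu <- pickMutation()
      used[mu$pos] <- TRUE
      tipSeqs[mut$carriers[[j]], mu$pos] <- mu$derived
      polyLog[j] <- mu$effect
    }
    ids <- sprintf("%s_%s_%02d", grp$species, grp$lineage,
                   seq_len(grp$n))
    seqNew <- apply(tipSeqs, 1L, paste, collapse = "")
    names(seqNew) <- ids
    seqs <- c(seqs, seqNew)
    lineageRows[[gIdx]] <- data.frame(sample_id = ids,
                                      species = grp$species,
                                      lineage = grp$lineage,
                                      stringsAsFactors = FALSE)
    mutLog[[paste(grp$species, grp$lineage, sep = "/")]] <-
      list(divergence = divLog, polymorphism = polyLog)
  }
  if (fallbackCount > 0L)
    warning(sprintf(
      "%d CDS mutation(s) fell back to an unconstrained change", fallbackCount))
  aln <- newAlignment(seqs)
  lineages <- do.call(rbind, lineageRows)
  out <- list(alignment = aln, ann = ann, lineages = lineages,
              mutations = mutLog, seed = as.integer(seed))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "alignment.fasta"),
                  gff = file.path(dir, "annotation.gff3"),
                  lineages = file.path(dir, "lineages.tsv"))
    writeAlignment(aln, paths$fasta)
    writeAnnotation(ann, paths$gff)
    utils::write.table(lineages, paths$lineages, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  invisible(out)
}
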