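# Per-group diversity statistics: segregating sites, singletons, shared
# polymorphisms, haplotype and nucleotide diversity, Watterson's theta,
# rarefied pi, and per-region-class diversity.
#
# Missing data policy: complete deletion -- any column containing a gap,
# N or IUPAC ambiguity in any sequence is excluded for all sequences
# before any statistic is computed.

# Per-column state counts over usable columns: 4 x L matrix of A/C/G/T
# counts, restricted to usable columns. Internal workhorse.
siteCounts <- function(codes) {
  keep <- usableColumns(codes)
  sub <- codes[, keep, drop = FALSE]
  cnt <- matrix(0L, nrow = 4L, ncol = ncol(sub))
  for (b in 1:4) cnt[b, ] <- colSums(sub == b)
  list(counts = cnt, usable = sum(keep), keep = keep)
}

#' Polymorphic-site summary
#'
#' Classifies usable alignment columns (complete deletion of columns with
#' gaps or ambiguities) into segregating sites, and segregating sites into
#' singletons (minor state carried by exactly one sequence) and shared
#' polymorphisms (minor state in two or more sequences). At a column with
#' more than two states the site is a singleton only if every non-major
#' state is carried by a single sequence.
#'
#' @param aln A [MitoAlignment] with at least two sequences.
#' @return A list with `S`, `singletons`, `sharedPoly`, `usableSites`,
#'   `eta` (total mutations, summing states-1 per site) and `etaS`
#'   (singleton mutations: derived states carried by one sequence).
#' @export
siteSummary <- function(aln) {
  codes <- baseCodeMatrix(aln)
  n <- nrow(codes)
  if (n < 2L) stopDegenerate("site summary needs n >= 2 sequences")
  sc <- siteCounts(codes)
  if (sc$usable == 0L) stopDegenerate("no usable (fully resolved) columns")
  cnt <- sc$counts
  nStates <- colSums(cnt > 0L)
  seg <- nStates >= 2L
  S <- sum(seg)
  # minor-state occupancy per segregating column
  singleton <- logical(ncol(cnt))
  for (j in which(seg)) {
    cs <- cnt[, j]
    cs <- cs[cs > 0L]
    minor <- cs[-which.max(cs)]
    singleton[j] <- all(minor == 1L)
  }
  etaS <- 0L
  for (j in which(seg)) {
    cs <- cnt[, j]
    cs <- cs[cs > 0L]
    # each state present in exactly one sequence is one singleton mutation
    # (for n = 2 a segregating site has two count-1 states but one mutation)
    if (n == 2L) etaS <- etaS + as.integer(any(cs == 1L))
    else etaS <- etaS + sum(cs == 1L)
  }
  list(S = S,
       singletons = sum(singleton),
       sharedPoly = S - sum(singleton),
       usableSites = sc$usable,
       eta = sum(pmax(nStates - 1L, 0L)),
       etaS = as.integer(etaS))
}

#' Haplotype count and diversity
#'
#' Haplotypes are distinct sequences over usable columns (so sequences
#' differing only at excluded columns collapse). Haplotype diversity is
#' Hd = n/(n-1) * (1 - sum p_i^2); its standard deviation follows Nei
#' (1987).
#'
#' @param aln A [MitoAlignment] with n >= 2.
#' @return List with `H`, `Hd`, `sdHd`.
#' @export
haplotypeSummary <- function(aln) {
  codes <- baseCodeMatrix(aln)
  n <- nrow(codes)
  if (n < 2L) stopDegenerate("haplotype summary needs n >= 2 sequences")
  keep <- usableColumns(codes)
  if (!any(keep)) stopDegenerate("no usable (fully resolved) columns")
  key <- apply(codes[, keep, drop = FALSE], 1L, paste, collapse = ",")
  counts <- table(key)
  p <- as.numeric(counts) / n
  sum2 <- sum(p^2)
  Hd <- n / (n - 1) * (1 - sum2)
  # Nei (1987) eq. 8.12 sampling variance of haplotype diversity
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - sum2^2) + sum2 - sum2^2)
  list(H = length(counts), Hd = Hd, sdHd = sqrt(max(v, 0)))
}

#' Nucleotide diversity (pi)
#'
#' Mean number of pairwise differences over usable columns across all
#' C(n,2) sequence pairs, totalled (`piTotal`) and per usable site
#' (`piPerSite`), with the Nei (1987, eq. 10.7) standard deviation of the
#' per-site value.
#'
#' @param aln A [MitoAlignment] with n >= 2.
#' @return List with `piPerSite`, `sdPi`, `piTotal`, `usableSites`.
#' @export
nucleotideDiversity <- function(aln) {
  codes <- baseCodeMatrix(aln)
  n <- nrow(codes)
  if (n < 2L) stopDegenerate("nucleotide diversity needs n >= 2 sequences")
  sc <- siteCounts(codes)
  if (sc$usable == 0L) stopDegenerate("no usable (fully resolved) columns")
  piTotal <- piTotalFromCounts(sc$counts, n)
  L <- sc$usable
  piSite <- piTotal / L
  # Nei (1987) eq. 10.7: V(pi) = (n+1)/(3(n-1)L) pi + 2(n^2+n+3)/(9n(n-1)) pi^2
  v <- (n + 1) / (3 * (n - 1) * L) * piSite +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * piSite^2
  list(piPerSite = piSite, sdPi = sqrt(max(v, 0)), piTotal = piTotal,
       usableSites = L)
}

# Mean pairwise differences from a 4 x L state-count matrix.
piTotalFromCounts <- function(cnt, n) {
  if (ncol(cnt) == 0L) return(0)
  same <- colSums(cnt * (cnt - 1L)) / 2
  sum(1 - same / choose(n, 2))
}

#' Watterson's estimator of theta
#'
#' theta_W = S / (a1 * L) with a1 = sum_{i=1}^{n-1} 1/i, per site.
#'
#' @param S Number of segregating sites.
#' @param n Number of sequences (>= 2).
#' @param usableSites Number of usable sites L.
#' @return theta_W per site.
#' @export
wattersonTheta <- function(S, n, usableSites) {
  if (n < 2L) stopDegenerate("Watterson's theta needs n >= 2")
  if (usableSites <= 0) stopDegenerate("usableSites must be positive")
  S / (harmonicA1(n) * usableSites)
}

#' All diversity statistics for one group and partition
#'
#' Bundles [siteSummary()], [haplotypeSummary()], [nucleotideDiversity()]
#' and [wattersonTheta()] into a one-row data.frame shaped like a summary
#' table row.
#'
#' @param aln A [MitoAlignment] with n >= 2.
#' @return One-row data.frame with columns `n`, `usable_sites`, `S`,
#'   `singletons`, `shared_poly`, `theta_w`, `pi`, `sd_pi`, `H`, `Hd`,
#'   `sd_Hd`.
#' @export
diversityStats <- function(aln) {
  ss <- siteSummary(aln)
  hs <- haplotypeSummary(aln)
  nd <- nucleotideDiversity(aln)
  data.frame(n = nSequences(aln), usable_sites = ss$usableSites, S = ss$S,
             singletons = ss$singletons, shared_poly = ss$sharedPoly,
             theta_w = wattersonTheta(ss$S, nSequences(aln), ss$usableSites),
             pi = nd$piPerSite, sd_pi = nd$sdPi, H = hs$H, Hd = hs$Hd,
             sd_Hd = hs$sdHd)
}

#' Rarefied nucleotide diversity
#'
#' Repeatedly subsamples `k` distinct sequences without replacement and
#' recomputes per-site pi within each subsample (usable columns are
#' re-evaluated inside the subsample), summarising the replicate
#' distribution by its median, mean and 95% percentile interval. This puts
#' groups of unequal sample size on a common footing.
#'
#' @param aln A [MitoAlignment] with n >= k.
#' @param k Subsample size (default 3).
#' @param B Number of replicates (default 2500).
#' @param seed Integer seed; identical seeds give identical results.
#' @return List with `k`, `B`, `piValues` (length B), `median`, `mean`,
#'   `ciLow`, `ciHigh` (2.5/97.5 percentiles) and `seed`.
#' @export
rarefiedPi <- function(aln, k = 3L, B = 2500L, seed = 1L) {
  n <- nSequences(aln)
  if (n < k) stopDegenerate("rarefaction needs n >= k (n=%d, k=%d)", n, k)
  codes <- baseCodeMatrix(aln)
  set.seed(seed)
  pis <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, k)
    piFromCodes(codes[idx, , drop = FALSE])
  }, 0)
  qs <- stats::quantile(pis, c(0.025, 0.975), names = FALSE, type = 7)
  list(k = as.integer(k), B = as.integer(B), piValues = pis,
       median = stats::median(pis), mean = mean(pis), ciLow = qs[1L],
       ciHigh = qs[2L], seed = as.integer(seed))
}

# per-site pi for a small integer-coded matrix (rows = sequences)
piFromCodes <- function(codes) {
  keep <- !apply(is.na(codes), 2L, any)
  L <- sum(keep)
  if (L == 0L) return(NA_real_)
  sub <- codes[, keep, drop = FALSE]
  n <- nrow(sub)
  tot <- 0
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      tot <- tot + sum(sub[i, ] != sub[j, ])
  tot / choose(n, 2) / L
}

#' Nucleotide diversity by region class
#'
#' Computes per-site pi over the union of columns of each feature class
#' (CDS, tRNA, rRNA, origin) plus the remaining `noncoding` columns,
#' profiling how molecular constraint varies along the genome.
#'
#' @param aln A [MitoAlignment].
#' @param ann Annotation from [geneAnnotation()].
#' @return data.frame with columns `klass`, `usable_sites`, `pi`; classes
#'   with no columns are absent from the result.
#' @export
regionDiversity <- function(aln, ann) {
  cm <- columnMap(aln)
  kl <- S4Vectors::mcols(ann)$klass
  st <- GenomicRanges::start(ann)
  en <- GenomicRanges::end(ann)
  codes <- baseCodeMatrix(aln)
  n <- nrow(codes)
  classes <- c("CDS", "tRNA", "rRNA", "origin")
  covered <- rep(FALSE, max(cm, en))
  rows <- list()
  for (cl in classes) {
    sel <- rep(FALSE, max(cm, en))
    for (i in which(kl == cl)) {
      sel[st[i]:en[i]] <- TRUE
      covered[st[i]:en[i]] <- TRUE
    }
    cols <- which(sel[cm])
    if (length(cols) == 0L) next
    sc <- siteCounts(codes[, cols, drop = FALSE])
    rows[[cl]] <- data.frame(klass = cl, usable_sites = sc$usable,
                             pi = if (sc$usable) piTotalFromCounts(sc$counts,
                                                                   n) /
                                    sc$usable else NA_real_)
  }
  cols <- which(!covered[cm])
  if (length(cols) > 0L) {
    sc <- siteCounts(codes[, cols, drop = FALSE])
    rows[["noncoding"]] <- data.frame(klass = "noncoding",
                                      usable_sites = sc$usable,
                                      pi = if (sc$usable)
                                        piTotalFromCounts(sc$counts, n) /
                                          sc$usable else NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Diversity table across groups and partitions
#'
#' Runs [diversityStats()] for every (species, lineage) group of a lineage
#' table and every requested partition, mirroring a per-lineage summary
#' table. Groups with fewer than 2 samples are skipped with a message.
#'
#' @param aln A [MitoAlignment] (whole-genome, already masked).
#' @param lineages Lineage table (see [lineageTable()]).
#' @param ann Annotation; required unless `partitions == "whole"`.
#' @param partitions Character subset of `c("whole", "noncoding",
#'   "cds_concat")`.
#' @param bySpecies Also aggregate lineages per species (default TRUE).
#' @return data.frame with one row per (group, partition).
#' @export
diversityTable <- function(aln, lineages, ann = NULL,
                           partitions = "whole", bySpecies = TRUE) {
  parts <- lapply(stats::setNames(partitions, partitions), function(p) {
    if (p == "whole") aln else extractPartition(aln, ann, p)
  })
  groups <- split(lineages$sample_id, lineages$lineage)
  labels <- data.frame(
    species = vapply(names(groups), function(g)
      lineages$species[match(g, lineages$lineage)], ""),
    lineage = names(groups), stringsAsFactors = FALSE)
  if (bySpecies) {
    spGroups <- split(lineages$sample_id, lineages$species)
    groups <- c(groups, spGroups)
    labels <- rbind(labels,
                    data.frame(species = names(spGroups),
                               lineage = "(all)", stringsAsFactors = FALSE))
  }
  rows <- list()
  for (i in seq_along(groups)) {
    ids <- intersect(groups[[i]], sampleIds(aln))
    if (length(ids) < 2L) {
      message(sprintf("group %s/%s skipped: n = %d < 2", labels$species[i],
                      labels$lineage[i], length(ids)))
      next
    }
    for (p in names(parts)) {
      st <- diversityStats(subsetSamples(parts[[p]], ids))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(species = labels$species[i],
                         lineage = labels$lineage[i], partition = p,
                         stringsAsFactors = FALSE), st)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
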