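# Codon-level selection analyses under the vertebrate mitochondrial code
# (NCBI translation table 2): Nei-Gojobori synonymous/nonsynonymous site
# and difference counting with pathway averaging, piN/piS,
# McDonald-Kreitman tests with the neutrality index, and the permutation
# group comparisons and correlations used across lineages.

# package-scope cache for per-code lookup tables
.codonCache <- new.env(parent = emptyenv())

codonTables <- function(codeId = "2") {
  key <- paste0("code", codeId)
  if (!is.null(.codonCache[[key]])) return(.codonCache[[key]])
  code <- Biostrings::getGeneticCode(codeId)
  codons <- names(code)
  bases <- c("A", "C", "G", "T")
  # per-codon fractional syn/nonsyn sites; changes to stops are excluded
  # from the denominator, so synSites + nonsynSites + stopFrac == 3 exactly
  synSites <- nonsynSites <- stopFrac <- stats::setNames(numeric(64), codons)
  for (cod in codons) {
    sp <- strsplit(cod, "")[[1]]
    for (p in 1:3) {
      for (b in setdiff(bases, sp[p])) {
        cod2 <- sp; cod2[p] <- b
        aa2 <- code[[paste(cod2, collapse = "")]]
        if (aa2 == "*" && code[[cod]] != "*") {
          stopFrac[cod] <- stopFrac[cod] + 1 / 3
        } else if (aa2 == code[[cod]]) {
          synSites[cod] <- synSites[cod] + 1 / 3
        } else {
          nonsynSites[cod] <- nonsynSites[cod] + 1 / 3
        }
      }
    }
  }
  tab <- list(code = code, synSites = synSites, nonsynSites = nonsynSites,
              stopFrac = stopFrac, stops = codons[code == "*"],
              pairDiff = new.env(parent = emptyenv()))
  .codonCache[[key]] <- tab
  tab
}

#' Synonymous and nonsynonymous site counts (Nei-Gojobori)
#'
#' For each codon, the synonymous site count is the summed fraction of
#' one-step changes per position that are synonymous under the genetic
#' code; changes that would create a stop codon are excluded from the
#' denominator, so per codon `syn + nonsyn + stop-excluded == 3` exactly.
#' For an alignment, sites are summed per sequence over its codons and
#' averaged over sequences.
#'
#' @param x A [CodonAlignment] or a character vector of codon strings
#'   (one sequence).
#' @param codeId NCBI translation-table id (default "2", vertebrate
#'   mitochondrial); ignored for a `CodonAlignment`, which carries its own.
#' @return List with `nonsynSites` (N) and `synSites` (S).
#' @export
countSynNonsynSites <- function(x, codeId = "2") {
  if (methods::is(x, "CodonAlignment")) {
    tab <- codonTables(x@geneticCode)
    tot <- c(N = 0, S = 0)
    for (g in x@genes) {
      if (ncol(g) == 0L) next
      tot["N"] <- tot["N"] + sum(tab$nonsynSites[g]) / nrow(g)
      tot["S"] <- tot["S"] + sum(tab$synSites[g]) / nrow(g)
    }
    return(list(nonsynSites = unname(tot["N"]), synSites = unname(tot["S"])))
  }
  tab <- codonTables(codeId)
  list(nonsynSites = sum(tab$nonsynSites[x]), synSites = sum(tab$synSites[x]))
}

# all orderings of positions, by number of differing positions
.pathPerms <- list(`1` = matrix(1L, 1, 1),
                   `2` = rbind(c(1L, 2L), c(2L, 1L)),
                   `3` = t(sapply(list(c(1,2,3), c(1,3,2), c(2,1,3),
                                       c(2,3,1), c(3,1,2), c(3,2,1)),
                                  as.integer)))

#' Synonymous/nonsynonymous differences between two codons
#'
#' Classifies the differences between two codons under the genetic code.
#' Codons differing at several positions are resolved by averaging over all
#' minimal mutational pathways, excluding pathways that pass through a stop
#' codon (Nei-Gojobori). If every pathway is blocked by stops the pair is
#' unresolvable and `NA`s are returned with a warning.
#'
#' @param a,b Three-letter codon strings over ACGT.
#' @param codeId NCBI translation-table id (default "2").
#' @return Numeric vector `c(nonsyn, syn)` (fractional for multi-step
#'   differences).
#' @export
countCodonDifferences <- function(a, b, codeId = "2") {
  tab <- codonTables(codeId)
  key <- paste0(a, b)
  hit <- tab$pairDiff[[key]]
  if (!is.null(hit)) return(hit)
  res <- codonPairDiff(a, b, tab)
  tab$pairDiff[[key]] <- res
  tab$pairDiff[[paste0(b, a)]] <- res
  res
}

codonPairDiff <- function(a, b, tab) {
  if (a == b) return(c(nonsyn = 0, syn = 0))
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  pos <- which(sa != sb)
  perms <- .pathPerms[[as.character(length(pos))]]
  totN <- 0; totS <- 0; nPaths <- 0L
  for (r in seq_len(nrow(perms))) {
    cur <- sa
    pN <- 0; pS <- 0; ok <- TRUE
    for (p in pos[perms[r, ]]) {
      nxt <- cur; nxt[p] <- sb[p]
      nxtStr <- paste(nxt, collapse = "")
      curStr <- paste(cur, collapse = "")
      if (nxtStr %in% tab$stops && nxtStr != b) { ok <- FALSE; break }
      if (tab$code[[nxtStr]] == tab$code[[curStr]]) pS <- pS + 1
      else pN <- pN + 1
      cur <- nxt
    }
    if (ok) { totN <- totN + pN; totS <- totS + pS; nPaths <- nPaths + 1L }
  }
  if (nPaths == 0L) {
    warning(sprintf("codon pair %s/%s: all pathways pass through stops", a,
                    b))
    return(c(nonsyn = NA_real_, syn = NA_real_))
  }
  c(nonsyn = totN / nPaths, syn = totS / nPaths)
}

#' Build a codon alignment from an annotated nucleotide alignment
#'
#' Extracts each CDS (minus-strand genes reverse-complemented), trims
#' incomplete terminal codons, projects the columns into codon triplets and
#' removes codon columns containing any gap or ambiguity in any sequence
#' (complete deletion at codon resolution, counted per gene). Internal stop
#' codons are reported as warnings, not errors.
#'
#' @param aln A [MitoAlignment].
#' @param ann Annotation with CDS features (see [geneAnnotation()]).
#' @param codeId NCBI translation-table id (default "2").
#' @return A [CodonAlignment].
#' @export
codonAlignment <- function(aln, ann, codeId = "2") {
  kl <- S4Vectors::mcols(ann)$klass
  nm <- S4Vectors::mcols(ann)$name
  tab <- codonTables(codeId)
  genes <- list(); dropped <- integer()
  for (i in which(kl == "CDS")) {
    sub <- suppressWarnings(
      extractPartition(aln, ann[i], "cds_concat"))
    m <- alignmentMatrix(sub)
    nc <- ncol(m) %/% 3L
    if (nc == 0L) { genes[[nm[i]]] <- matrix("", nSequences(aln), 0L); next }
    cod <- matrix("", nrow = nrow(m), ncol = nc)
    for (j in seq_len(nc))
      cod[, j] <- paste0(m[, 3L * j - 2L], m[, 3L * j - 1L], m[, 3L * j])
    usable <- !apply(cod, 2L, function(cc) any(!cc %in% names(tab$code)))
    dropped[nm[i]] <- sum(!usable)
    cod <- cod[, usable, drop = FALSE]
    internal <- cod[, seq_len(max(ncol(cod) - 1L, 0L)), drop = FALSE]
    if (ncol(internal) && any(tab$code[internal] == "*")) {
      w <- which(matrix(tab$code[internal] == "*", nrow(internal)),
                 arr.ind = TRUE)
      warning(sprintf("gene '%s': internal stop codon (e.g. seq %d, codon %d)",
                      nm[i], w[1, 1], w[1, 2]))
    }
    genes[[nm[i]]] <- cod
  }
  if (length(genes) == 0L) stopInput("annotation contains no CDS features")
  methods::new("CodonAlignment", genes = genes, sampleIds = sampleIds(aln),
               geneticCode = codeId, dropped = dropped)
}

# subset a CodonAlignment by sample ids
subsetCodons <- function(caln, ids) {
  idx <- match(ids, caln@sampleIds)
  if (anyNA(idx)) stopInput("samples not in codon alignment")
  methods::new("CodonAlignment",
               genes = lapply(caln@genes, function(g) g[idx, , drop = FALSE]),
               sampleIds = ids, geneticCode = caln@geneticCode,
               dropped = caln@dropped)
}

#' Nonsynonymous and synonymous nucleotide diversity (piN/piS)
#'
#' Mean pairwise nonsynonymous (synonymous) differences over all C(n,2)
#' sequence pairs, divided by the mean nonsynonymous (synonymous) site
#' count. A ratio is undefined (NA, with `ratioDefined = FALSE`) when
#' piS = 0.
#'
#' @param caln A [CodonAlignment] with n >= 2.
#' @return List with `piN`, `piS`, `ratio`, `ratioDefined`, and the raw
#'   mean pairwise difference counts `meanNonsynDiffs`, `meanSynDiffs`.
#' @export
piNpiS <- function(caln) {
  n <- length(caln@sampleIds)
  if (n < 2L) stopDegenerate("piN/piS needs n >= 2 sequences")
  sites <- countSynNonsynSites(caln)
  nPairs <- choose(n, 2)
  totN <- 0; totS <- 0
  for (g in caln@genes) {
    if (ncol(g) == 0L) next
    for (j in seq_len(ncol(g))) {
      col <- g[, j]
      if (length(unique(col)) == 1L) next
      for (i1 in seq_len(n - 1L)) for (i2 in (i1 + 1L):n) {
        if (col[i1] == col[i2]) next
        d <- countCodonDifferences(col[i1], col[i2], caln@geneticCode)
        if (anyNA(d)) next
        totN <- totN + d[["nonsyn"]]; totS <- totS + d[["syn"]]
      }
    }
  }
  piN <- (totN / nPairs) / sites$nonsynSites
  piS <- (totS / nPairs) / sites$synSites
  list(piN = piN, piS = piS,
       ratio = if (piS > 0) piN / piS else NA_real_,
       ratioDefined = piS > 0,
       meanNonsynDiffs = totN / nPairs, meanSynDiffs = totS / nPairs)
}

# majority consensus codon of a character vector (ties: first-sorted)
consensusCodon <- function(x, valid) {
  x <- x[x %in% valid]
  if (length(x) == 0L) return(NA_character_)
  if (!any(x != x[1L])) return(x[1L])
  tb <- sort(table(x), decreasing = TRUE)
  names(tb)[1L]
}

#' McDonald-Kreitman test
#'
#' Contrasts fixed differences between an ingroup and an outgroup with
#' polymorphism inside the ingroup, at synonymous and nonsynonymous sites
#' of the protein-coding genes. A codon column is polymorphic if it
#' segregates within the ingroup; it is a fixed difference if all ingroup
#' sequences share a codon that differs from the outgroup consensus.
#' Codons that are both polymorphic and divergent count as polymorphism
#' only. The neutrality index is NI = (Pn/Ps)/(Dn/Ds); significance comes
#' from a G-test (without Williams correction by default) and a two-sided
#' Fisher exact test on the 2x2 table of counts rounded half-to-even (the
#' fractional pathway-averaged counts themselves are used for NI).
#'
#' @param ingroup,outgroup [CodonAlignment] objects over the same gene set
#'   and codon coordinates (build both from the same annotation).
#' @param williams Apply the Williams correction to the G statistic?
#' @param haldane Add 0.5 to every cell for NI when a cell is zero
#'   (Haldane correction)? Off by default.
#' @return List with `table` (Dn, Ds, Pn, Ps, fractional), `rounded`
#'   (integer 2x2), `NI`, `NIdefined`, `G`, `pG`, `pFisher`,
#'   `interpretation` (`positive` / `neutral` / `purifying`), `degenerate`.
#' @export
mkTest <- function(ingroup, outgroup, williams = FALSE, haldane = FALSE) {
  if (!identical(names(ingroup@genes), names(outgroup@genes)))
    stopInput("ingroup and outgroup must cover the same genes")
  codeId <- ingroup@geneticCode
  tab <- codonTables(codeId)
  valid <- names(tab$code)
  Dn <- Ds <- Pn <- Ps <- 0
  for (g in names(ingroup@genes)) {
    gi <- ingroup@genes[[g]]; go <- outgroup@genes[[g]]
    if (ncol(gi) != ncol(go))
      stopInput("gene '%s': codon coordinates differ between ingroup and outgroup", g)
    for (j in seq_len(ncol(gi))) {
      colIn <- gi[, j]
      states <- unique(colIn)
      if (length(states) > 1L) {
        # polymorphic: star from the major codon to each minor codon
        major <- consensusCodon(colIn, valid)
        for (s in setdiff(states, major)) {
          d <- countCodonDifferences(major, s, codeId)
          if (anyNA(d)) next
          Pn <- Pn + d[["nonsyn"]]; Ps <- Ps + d[["syn"]]
        }
      } else {
        out <- consensusCodon(go[, j], valid)
        if (is.na(out) || out == states) next
        d <- countCodonDifferences(states, out, codeId)
        if (anyNA(d)) next
        Dn <- Dn + d[["nonsyn"]]; Ds <- Ds + d[["syn"]]
      }
    }
  }
  degenerate <- (Dn + Ds + Pn + Ps) == 0
  niTable <- c(Dn = Dn, Ds = Ds, Pn = Pn, Ps = Ps)
  niCells <- if (haldane && any(niTable == 0)) niTable + 0.5 else niTable
  NIdefined <- niCells[["Ps"]] > 0 && niCells[["Dn"]] > 0 &&
    niCells[["Ds"]] > 0
  NI <- if (NIdefined)
    (niCells[["Pn"]] / niCells[["Ps"]]) / (niCells[["Dn"]] / niCells[["Ds"]])
  else NA_real_
  rounded <- matrix(as.integer(round(c(Dn, Ds, Pn, Ps))), nrow = 2L,
                    dimnames = list(c("nonsyn", "syn"),
                                    c("fixed", "polymorphic")))
  gres <- gTest2x2(rounded, williams = williams)
  pFisher <- if (degenerate) NA_real_ else
    stats::fisher.test(rounded)$p.value
  interp <- if (!NIdefined || degenerate) NA_character_
            else if (NI > 1) "purifying" else if (NI < 1) "positive"
            else "neutral"
  list(table = niTable, rounded = rounded, NI = unname(NI),
       NIdefined = unname(NIdefined), G = gres$G, pG = gres$p,
       pFisher = pFisher, interpretation = interp, degenerate = degenerate)
}

# likelihood-ratio G-test on a 2x2 table
gTest2x2 <- function(m, williams = FALSE) {
  if (sum(m) == 0 || any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(G = NA_real_, p = NA_real_))
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  terms <- ifelse(m > 0, m * log(m / E), 0)
  G <- 2 * sum(terms)
  if (williams) {
    q <- 1 + ((sum(m) / rowSums(m)[1] + sum(m) / rowSums(m)[2] - 1) *
              (sum(m) / colSums(m)[1] + sum(m) / colSums(m)[2] - 1)) /
      (6 * sum(m))
    G <- G / q
  }
  list(G = unname(G), p = unname(stats::pchisq(G, df = 1,
                                               lower.tail = FALSE)))
}

#' Permutation one-way group comparison (PERMANOVA-style)
#'
#' One-way F-type statistic on the observations, with the null distribution
#' obtained by randomly permuting group labels; p = (1 + #{perm >=
#' observed}) / (nPerm + 1). All pairwise group contrasts are tested the
#' same way and adjusted by Benjamini-Hochberg FDR. Groups with fewer than
#' two observations are dropped with a warning.
#'
#' @param values Numeric observations.
#' @param labels Group labels (same length).
#' @param nPerm Number of permutations (default 9999).
#' @param seed Integer seed.
#' @return List with `stat`, `pvalue`, and `pairwise` (data.frame with
#'   group pair, F, raw and FDR-adjusted p).
#' @export
permutationGroupTest <- function(values, labels, nPerm = 9999L, seed = 1L) {
  labels <- as.character(labels)
  keepLvl <- names(which(table(labels) >= 2L))
  if (length(keepLvl) < length(unique(labels)))
    warning("groups with < 2 observations excluded: ",
            paste(setdiff(unique(labels), keepLvl), collapse = ", "))
  keep <- labels %in% keepLvl
  values <- values[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2L)
    stopDegenerate("need >= 2 groups with >= 2 observations")
  set.seed(seed)
  fStat <- function(v, l) {
    gm <- tapply(v, l, mean); gn <- tapply(v, l, length)
    ssb <- sum(gn * (gm - mean(v))^2)
    ssw <- sum((v - gm[l])^2)
    k <- length(gm); n <- length(v)
    if (ssw == 0) return(Inf)
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  obs <- fStat(values, labels)
  perm <- vapply(seq_len(nPerm), function(i)
    fStat(values, sample(labels)), 0)
  p <- (1 + sum(perm >= obs)) / (nPerm + 1)
  lvls <- sort(unique(labels))
  pairs <- utils::combn(lvls, 2L)
  pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                   F = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    sel <- labels %in% pairs[, i]
    v <- values[sel]; l <- labels[sel]
    o <- fStat(v, l)
    pm <- vapply(seq_len(nPerm), function(j) fStat(v, sample(l)), 0)
    pw$F[i] <- o
    pw$p[i] <- (1 + sum(pm >= o)) / (nPerm + 1)
  }
  pw$p_adj <- stats::p.adjust(pw$p, method = "BH")
  list(stat = obs, pvalue = p, pairwise = pw)
}

#' Pearson correlation test
#'
#' Thin wrapper around [stats::cor.test()] returning the coefficient and
#' t-distribution p-value, with an explicit undefined flag for
#' zero-variance input (as arises when a lineage shows no variation).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `r`, `pvalue`, `defined`.
#' @export
correlationTest <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stopInput("correlationTest needs equal lengths >= 3")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stopInput("correlationTest needs finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, pvalue = NA_real_, defined = FALSE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), pvalue = ct$p.value, defined = TRUE)
}
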