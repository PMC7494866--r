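#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   getGeneticCode
#' @importFrom GenomicRanges GRanges start end strand
#' @importFrom IRanges IRanges reduce
#' @importFrom S4Vectors mcols
NULL

#' MitoAlignment: a multiple alignment of mitochondrial genomes
#'
#' Holds one aligned sequence per individual together with a per-column map
#' back to the coordinates of the original (unmasked) alignment, so that
#' annotation intervals given on original coordinates remain resolvable
#' after columns have been removed.
#'
#' @slot seqs A [Biostrings::DNAStringSet] of equal-width aligned sequences;
#'   names are sample identifiers.
#' @slot columnMap Integer vector, one entry per alignment column, giving the
#'   1-based coordinate of that column in the original alignment.
#' @export
setClass("MitoAlignment",
  representation(seqs = "DNAStringSet", columnMap = "integer"))

setValidity("MitoAlignment", function(object) {
  w <- Biostrings::width(object@seqs)
  if (length(object@seqs) < 1L) return("alignment must contain >= 1 record")
  if (length(unique(w)) > 1L)
    return("all aligned sequences must have identical length")
  ids <- names(object@seqs)
  if (is.null(ids) || anyDuplicated(ids))
    return("sample identifiers must be present and unique")
  if (length(object@columnMap) != w[1L])
    return("columnMap length must equal the alignment width")
  TRUE
})

#' @describeIn MitoAlignment Number of sequences and columns.
#' @param object,x A `MitoAlignment`.
#' @export
setMethod("show", "MitoAlignment", function(object) {
  cat("MitoAlignment with", length(object@seqs), "sequences x",
      alignmentWidth(object), "columns\n")
  cat("  samples:", paste(utils::head(names(object@seqs), 4L),
                          collapse = ", "),
      if (length(object@seqs) > 4L) "..." else "", "\n")
})

#' Accessors for MitoAlignment
#'
#' @param x A `MitoAlignment`.
#' @return `alignmentSeqs()` the `DNAStringSet`; `columnMap()` the integer
#'   coordinate map; `sampleIds()` the sample names; `alignmentWidth()` /
#'   `nSequences()` the dimensions.
#' @export
alignmentSeqs <- function(x) x@seqs

#' @rdname alignmentSeqs
#' @export
columnMap <- function(x) x@columnMap

#' @rdname alignmentSeqs
#' @export
sampleIds <- function(x) names(x@seqs)

#' @rdname alignmentSeqs
#' @export
alignmentWidth <- function(x) {
  if (length(x@seqs) == 0L) 0L else Biostrings::width(x@seqs)[1L]
}

#' @rdname alignmentSeqs
#' @export
nSequences <- function(x) length(x@seqs)

#' CodonAlignment: per-gene codon columns for protein-coding genes
#'
#' Codon-projected view of the CDS partition: one character matrix of codon
#' strings per gene (sequences x codon columns). Codon columns in which any
#' sequence carries a gap or ambiguity are removed at construction (complete
#' deletion at codon resolution) and counted in `dropped`.
#'
#' @slot genes Named list of character matrices (n x codons), entries are
#'   three-letter codon strings.
#' @slot sampleIds Character vector of sequence identifiers (row order of
#'   every gene matrix).
#' @slot geneticCode NCBI translation-table identifier (default "2",
#'   vertebrate mitochondrial).
#' @slot dropped Named integer: codon columns removed per gene because of
#'   unusable bases.
#' @export
setClass("CodonAlignment",
  representation(genes = "list", sampleIds = "character",
                 geneticCode = "character", dropped = "integer"))

setValidity("CodonAlignment", function(object) {
  for (g in names(object@genes)) {
    m <- object@genes[[g]]
    if (!is.matrix(m) || !is.character(m))
      return(sprintf("gene '%s' is not a character matrix", g))
    if (nrow(m) != length(object@sampleIds))
      return(sprintf("gene '%s' row count != number of samples", g))
    if (ncol(m) > 0L && any(nchar(m) != 3L))
      return(sprintf("gene '%s' contains non-triplet entries", g))
  }
  TRUE
})

#' @describeIn CodonAlignment Compact display.
#' @param object A `CodonAlignment`.
#' @export
setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment:", length(object@sampleIds), "sequences,",
      length(object@genes), "genes,",
      sum(vapply(object@genes, ncol, 0L)), "codon columns",
      sprintf("(code table %s)\n", object@geneticCode))
  if (sum(object@dropped) > 0L)
    cat("  ", sum(object@dropped), "codon columns dropped (unusable bases)\n")
})

#' MismatchFit: fitted pairwise-difference (mismatch) distribution
#'
#' Result of fitting the sudden-expansion (or constant-size) model to an
#' observed histogram of pairwise nucleotide differences, with parametric
#' bootstrap confidence intervals and the SSD goodness-of-fit test.
#'
#' @slot observed Histogram of pairwise difference counts (index 1 = zero
#'   differences); numeric so exact model expectations can be refit too.
#' @slot model `"constant"` or `"sudden_expansion"`.
#' @slot theta0,theta1,tau Fitted parameters: diversity before / after the
#'   size change and the change date in mutational units (tau = 2*mu*t).
#' @slot ssd Sum of squared deviations between observed and fitted
#'   mismatch frequencies.
#' @slot ci Numeric matrix (parameters x c(lower, upper)), 95% percentile
#'   bootstrap bounds; zero rows if no bootstrap was run.
#' @slot pSsd Bootstrap goodness-of-fit p-value (NA without bootstrap).
#' @slot B Number of bootstrap replicates performed.
#' @slot seed Seed used for the bootstrap.
#' @slot nSeq Number of sequences behind the histogram.
#' @slot converged Logical: did at least one optimizer start converge.
#' @export
setClass("MismatchFit",
  representation(observed = "numeric", model = "character",
                 theta0 = "numeric", theta1 = "numeric", tau = "numeric",
                 ssd = "numeric", ci = "matrix", pSsd = "numeric",
                 B = "integer", seed = "integer", nSeq = "integer",
                 converged = "logical"))

setValidity("MismatchFit", function(object) {
  if (any(c(object@theta0, object@theta1, object@tau) < 0))
    return("theta0, theta1 and tau must be >= 0")
  if (!object@model %in% c("constant", "sudden_expansion"))
    return("model must be 'constant' or 'sudden_expansion'")
  if (nrow(object@ci) > 0L && any(object@ci[, 1L] > object@ci[, 2L],
                                  na.rm = TRUE))
    return("confidence bounds must be ordered")
  TRUE
})

#' @describeIn MismatchFit Display fitted parameters and fit diagnostics.
#' @param object A `MismatchFit`.
#' @export
setMethod("show", "MismatchFit", function(object) {
  cat(sprintf("MismatchFit [%s] on %d pairwise comparisons (n = %d)\n",
              object@model, sum(object@observed), object@nSeq))
  cat(sprintf("  theta0 = %.4g  theta1 = %.4g  tau = %.4g  SSD = %.4g\n",
              object@theta0, object@theta1, object@tau, object@ssd))
  if (nrow(object@ci) > 0L) {
    cat(sprintf("  bootstrap (B = %d): p(SSD) = %.4g\n", object@B,
                object@pSsd))
    for (p in rownames(object@ci))
      cat(sprintf("    %s 95%% CI [%.4g, %.4g]\n", p, object@ci[p, 1L],
                  object@ci[p, 2L]))
  }
})

#' Genealogy: a coalescent tree over n sampled lineages
#'
#' Rooted binary genealogy in parent-pointer form. Nodes 1..n are tips,
#' nodes (n+1)..(2n-1) internal, node 2n-1 the root. Times are in coalescent
#' units (pairwise coalescence rate 1 in the present-day population).
#'
#' @slot n Number of tips.
#' @slot parent Integer parent pointer per node (0 for the root).
#' @slot nodeTime Numeric time of each node (tips at 0).
#' @export
setClass("Genealogy",
  representation(n = "integer", parent = "integer", nodeTime = "numeric"))

setValidity("Genealogy", function(object) {
  n <- object@n
  if (n < 2L) return("a genealogy needs at least 2 tips")
  if (length(object@parent) != 2L * n - 1L ||
      length(object@nodeTime) != 2L * n - 1L)
    return("parent/nodeTime must have length 2n-1")
  if (object@parent[2L * n - 1L] != 0L) return("last node must be the root")
  bl <- branchLengths(object)
  if (any(bl < 0)) return("branch lengths must be >= 0")
  TRUE
})

#' @describeIn Genealogy Display tip count and tree height.
#' @param object A `Genealogy`.
#' @export
setMethod("show", "Genealogy", function(object) {
  cat(sprintf("Genealogy with %d tips, T_MRCA = %.4g coalescent units\n",
              object@n, tMRCA(object)))
})

#' Genealogy accessors
#'
#' @param g A [Genealogy].
#' @return `branchLengths()`: numeric vector over non-root nodes (length
#'   2n-2), the length of the branch above each node; `tMRCA()`: root time;
#'   `totalLength()`: summed branch length.
#' @export
branchLengths <- function(g) {
  nn <- 2L * g@n - 2L
  g@nodeTime[g@parent[seq_len(nn)]] - g@nodeTime[seq_len(nn)]
}

#' @rdname branchLengths
#' @export
tMRCA <- function(g) g@nodeTime[2L * g@n - 1L]

#' @rdname branchLengths
#' @export
totalLength <- function(g) sum(branchLengths(g))
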