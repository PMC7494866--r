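#' Read a multiple alignment of mitochondrial genomes
#'
#' Reads a FASTA alignment (one record per individual), uppercases the
#' bases, converts U to T, and validates that every record has the same
#' length and that all characters are IUPAC nucleotide codes or gaps. The
#' returned alignment carries an identity column map (column i = original
#' coordinate i).
#'
#' @param path Path to a FASTA file.
#' @return A [MitoAlignment].
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "ACGA"), fa)
#' readAlignment(fa)
readAlignment <- function(path) {
  if (!file.exists(path)) stopInput("alignment file not found: %s", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stopInput("empty alignment file: %s", path)
  seqs <- chartr("u", "t", toupper(as.character(raw)))
  seqs <- chartr("U", "T", seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L)
    stopShape("aligned records differ in length (%s)",
              paste(range(widths), collapse = " vs "))
  bad <- gsub(paste0("[", paste(IUPAC_CHARS, collapse = ""), "]"), "", seqs)
  if (any(nchar(bad) > 0L)) {
    i <- which(nchar(bad) > 0L)[1L]
    ch <- substr(bad[i], 1L, 1L)
    col <- regexpr(ch, seqs[i], fixed = TRUE)
    stopInput("non-IUPAC character '%s' in record '%s' at column %d",
              ch, names(raw)[i], col)
  }
  newAlignment(seqs, ids = names(raw))
}

#' Write an alignment to FASTA
#'
#' @param aln A [MitoAlignment].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  Biostrings::writeXStringSet(alignmentSeqs(aln), path)
  invisible(path)
}

#' Read a mask (excluded intervals) from a BED file
#'
#' BED intervals (0-based half-open) are converted to the package's internal
#' 1-based inclusive convention and normalized (sorted, merged).
#'
#' @param path Path to a BED file.
#' @return An [IRanges::IRanges] of 1-based inclusive intervals.
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stopInput("mask file not found: %s", path)
  gr <- rtracklayer::import(path, format = "BED")
  IRanges::reduce(IRanges::IRanges(start = GenomicRanges::start(gr),
                                   end = GenomicRanges::end(gr)))
}

#' Build a mask from explicit coordinates
#'
#' Convenience constructor for masks given on original alignment
#' coordinates, e.g. the repetitive control-region segment excluded from
#' whole-mitogenome analyses. The boundary convention is configurable
#' because interval ends quoted in the literature are sometimes inclusive
#' and sometimes half-open; with `inclusive = FALSE` the `end` column is
#' treated as exclusive.
#'
#' @param start,end Integer vectors of interval bounds (1-based).
#' @param inclusive Logical; is `end` included in the interval?
#' @return An [IRanges::IRanges].
#' @export
maskIntervals <- function(start, end, inclusive = TRUE) {
  if (any(start < 1L) || any(end < start - !inclusive))
    stopRange("invalid mask interval")
  e <- if (inclusive) end else end - 1L
  IRanges::reduce(IRanges::IRanges(start = as.integer(start),
                                   end = as.integer(e)))
}

#' Remove masked columns from an alignment
#'
#' Columns whose original coordinate falls inside a mask interval are
#' removed; the column map of the surviving columns is preserved, so
#' annotations on original coordinates remain resolvable. The input object
#' is not modified.
#'
#' @param aln A [MitoAlignment].
#' @param mask An [IRanges::IRanges] on original coordinates (1-based
#'   inclusive), e.g. from [readMask()] or [maskIntervals()].
#' @return A [MitoAlignment] without the masked columns.
#' @export
applyMask <- function(aln, mask) {
  if (length(mask) == 0L) return(aln)
  cm <- columnMap(aln)
  maxCoord <- max(cm)
  if (any(IRanges::start(mask) < 1L) || any(IRanges::end(mask) > maxCoord))
    stopRange("mask interval outside genome coordinates (1..%d)", maxCoord)
  masked <- rep(FALSE, maxCoord)
  for (i in seq_along(mask))
    masked[IRanges::start(mask)[i]:IRanges::end(mask)[i]] <- TRUE
  keep <- !masked[cm]
  if (all(keep)) return(aln)
  m <- alignmentMatrix(aln)[, keep, drop = FALSE]
  newAlignment(apply(m, 1L, paste, collapse = ""), ids = sampleIds(aln),
               columnMap = cm[keep])
}

#' Read a gene annotation (GFF3 or 5-column TSV)
#'
#' Accepts either GFF3 (feature names taken from the `Name` or `ID`
#' attribute, classes from the `type` column) or a headered TSV with
#' columns `name`, `start`, `end`, `strand`, `klass`. Feature classes are
#' normalized to `CDS`, `tRNA`, `rRNA`, `origin` or `noncoding`.
#'
#' @param path Path to the annotation file.
#' @return A [GenomicRanges::GRanges] with metadata columns `name` and
#'   `klass`.
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stopInput("annotation file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "GFF3")
    nm <- S4Vectors::mcols(gr)$Name
    if (is.null(nm)) nm <- S4Vectors::mcols(gr)$ID
    kl <- as.character(S4Vectors::mcols(gr)$type)
    df <- data.frame(name = as.character(nm),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     klass = kl, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("name", "start", "end", "strand", "klass")
    if (!all(need %in% names(df)))
      stopInput("annotation TSV must have columns %s",
                paste(need, collapse = ", "))
  }
  geneAnnotation(df$name, df$start, df$end, df$strand, df$klass)
}

#' Construct a gene annotation
#'
#' @param name Unique feature names.
#' @param start,end 1-based inclusive coordinates on the original alignment.
#' @param strand `"+"` or `"-"` per feature.
#' @param klass Feature class: `CDS`, `tRNA`, `rRNA`, `origin` or
#'   `noncoding`.
#' @return A [GenomicRanges::GRanges] with `name` and `klass` metadata.
#' @export
geneAnnotation <- function(name, start, end, strand, klass) {
  klass <- sub("^trna$", "tRNA", sub("^rrna$", "rRNA", tolower(klass)))
  klass <- sub("^cds$", "CDS", klass)
  ok <- klass %in% c("CDS", "tRNA", "rRNA", "origin", "noncoding")
  if (!all(ok))
    stopInput("unknown feature class: %s",
              paste(unique(klass[!ok]), collapse = ", "))
  if (anyDuplicated(name))
    stopInput("duplicate feature name: %s",
              paste(unique(name[duplicated(name)]), collapse = ", "))
  if (any(start > end)) stopRange("feature start > end")
  if (any(start < 1L)) stopRange("feature start < 1")
  gr <- GenomicRanges::GRanges("genome",
                               IRanges::IRanges(as.integer(start),
                                                as.integer(end)),
                               strand = strand)
  S4Vectors::mcols(gr)$name <- as.character(name)
  S4Vectors::mcols(gr)$klass <- klass
  gr
}

#' Write an annotation to GFF3
#'
#' @param ann Annotation from [geneAnnotation()] / [readAnnotation()].
#' @param path Output path (`.gff3`).
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(ann, path) {
  gr <- ann
  S4Vectors::mcols(gr) <- NULL
  S4Vectors::mcols(gr)$source <- "porpopgen"
  S4Vectors::mcols(gr)$type <- S4Vectors::mcols(ann)$klass
  S4Vectors::mcols(gr)$Name <- S4Vectors::mcols(ann)$name
  S4Vectors::mcols(gr)$ID <- S4Vectors::mcols(ann)$name
  S4Vectors::mcols(gr)$phase <- ifelse(S4Vectors::mcols(ann)$klass == "CDS",
                                       0L, NA_integer_)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

featureColumns <- function(aln, start, end) {
  which(columnMap(aln) >= start & columnMap(aln) <= end)
}

#' Extract an analysis partition from an annotated alignment
#'
#' Builds the three alignment partitions used throughout the analyses:
#' \describe{
#'   \item{`whole`}{the input alignment unchanged;}
#'   \item{`noncoding`}{all columns not covered by any CDS/tRNA/rRNA/origin
#'     feature, in genomic order (intergenic spacers and the control
#'     region);}
#'   \item{`cds_concat`}{the protein-coding genes concatenated in annotation
#'     order, each gene's reading frame starting at its own first codon.
#'     Minus-strand genes (e.g. ND6) are reverse-complemented so codon
#'     positions are assignable; columns shared by overlapping genes (e.g.
#'     the ND5/ND6 overlap) appear once per gene, so the concatenated length
#'     is the sum of gene lengths, not the union.}
#' }
#' A terminal codon left incomplete after extraction (common for
#' mitochondrial CDSs with incomplete stop codons) is dropped with a
#' warning.
#'
#' @param aln A [MitoAlignment].
#' @param ann Annotation from [geneAnnotation()].
#' @param which One of `"whole"`, `"noncoding"`, `"cds_concat"`.
#' @return A [MitoAlignment] for the requested partition.
#' @export
extractPartition <- function(aln, ann,
                             which = c("whole", "noncoding", "cds_concat")) {
  which <- match.arg(which)
  if (which == "whole") return(aln)
  cm <- columnMap(aln)
  st <- GenomicRanges::start(ann)
  en <- GenomicRanges::end(ann)
  kl <- S4Vectors::mcols(ann)$klass
  nm <- S4Vectors::mcols(ann)$name
  strd <- as.character(GenomicRanges::strand(ann))
  m <- alignmentMatrix(aln)

  if (which == "noncoding") {
    covered <- rep(FALSE, max(cm, en))
    for (i in which(kl %in% c("CDS", "tRNA", "rRNA", "origin")))
      covered[st[i]:en[i]] <- TRUE
    keep <- !covered[cm]
    sub <- m[, keep, drop = FALSE]
    return(newAlignment(apply(sub, 1L, paste, collapse = ""),
                        ids = sampleIds(aln), columnMap = cm[keep]))
  }

  # cds_concat
  idx <- which(kl == "CDS")
  if (length(idx) == 0L) stopInput("annotation contains no CDS features")
  blocks <- list(); maps <- list()
  for (i in idx) {
    cols <- featureColumns(aln, st[i], en[i])
    if (length(cols) == 0L)
      stopRange("gene '%s' (%d-%d) outside the alignment", nm[i], st[i],
                en[i])
    block <- m[, cols, drop = FALSE]
    map <- cm[cols]
    if (strd[i] == "-") {
      block <- block[, rev(seq_len(ncol(block))), drop = FALSE]
      block[] <- chartr(COMPLEMENT_FROM, COMPLEMENT_TO, block)
      map <- rev(map)
    }
    extra <- ncol(block) %% 3L
    if (extra != 0L) {
      warning(sprintf(
        "gene '%s': length %d not a multiple of 3; dropping %d-bp incomplete terminal codon",
        nm[i], ncol(block), extra))
      keep <- seq_len(ncol(block) - extra)
      block <- block[, keep, drop = FALSE]
      map <- map[keep]
    }
    blocks[[nm[i]]] <- block
    maps[[nm[i]]] <- map
  }
  all <- do.call(cbind, blocks)
  newAlignment(apply(all, 1L, paste, collapse = ""), ids = sampleIds(aln),
               columnMap = unlist(maps, use.names = FALSE))
}

#' Read a sample-to-lineage table
#'
#' Reads a TSV with columns `sample_id`, `species`, `lineage` (every sample
#' in exactly one row; lineages nested within species).
#'
#' @param path Path to the TSV.
#' @return A validated data.frame.
#' @export
readLineageTable <- function(path) {
  if (!file.exists(path)) stopInput("lineage table not found: %s", path)
  if (file.size(path) == 0L) stopInput("empty lineage table: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lineageTable(df)
}

#' Validate a lineage table
#'
#' @param df A data.frame with columns `sample_id`, `species`, `lineage`.
#' @return The validated data.frame.
#' @export
lineageTable <- function(df) {
  need <- c("sample_id", "species", "lineage")
  if (!all(need %in% names(df)))
    stopInput("lineage table must have columns %s",
              paste(need, collapse = ", "))
  if (nrow(df) == 0L) stopInput("lineage table has no rows")
  if (anyDuplicated(df$sample_id))
    stopInput("duplicate sample_id in lineage table: %s",
              paste(unique(df$sample_id[duplicated(df$sample_id)]),
                    collapse = ", "))
  sp <- tapply(df$species, df$lineage, function(x) length(unique(x)))
  if (any(sp > 1L))
    stopInput("lineage assigned to multiple species: %s",
              paste(names(sp)[sp > 1L], collapse = ", "))
  df[, need]
}

#' Check lineage-table sample ids against an alignment
#'
#' @param df Lineage table (see [lineageTable()]).
#' @param aln A [MitoAlignment].
#' @return Invisibly, a list with `missing_in_alignment` and
#'   `missing_in_table` id vectors (both empty when consistent).
#' @export
validateLineages <- function(df, aln) {
  ids <- sampleIds(aln)
  out <- list(missing_in_alignment = setdiff(df$sample_id, ids),
              missing_in_table = setdiff(ids, df$sample_id))
  if (length(out$missing_in_alignment))
    warning("lineage table samples absent from alignment: ",
            paste(out$missing_in_alignment, collapse = ", "))
  if (length(out$missing_in_table))
    warning("alignment samples absent from lineage table: ",
            paste(out$missing_in_table, collapse = ", "))
  invisible(out)
}

#' Subset an alignment to a set of samples
#'
#' @param aln A [MitoAlignment].
#' @param ids Sample identifiers to keep (order preserved as given).
#' @return A [MitoAlignment].
#' @export
subsetSamples <- function(aln, ids) {
  missing <- setdiff(ids, sampleIds(aln))
  if (length(missing))
    stopInput("samples not in alignment: %s", paste(missing, collapse = ", "))
  methods::new("MitoAlignment", seqs = alignmentSeqs(aln)[ids],
               columnMap = columnMap(aln))
}
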