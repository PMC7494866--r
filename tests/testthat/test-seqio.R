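test_that("FASTA reading validates shape, characters and case", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgu", ">b", "ACGA"), fa)
  aln <- readAlignment(fa)
  expect_equal(nSequences(aln), 2L)
  expect_equal(alignmentWidth(aln), 4L)
  expect_equal(as.character(alignmentSeqs(aln)[["a"]]), "ACGT")  # u -> T
  expect_equal(columnMap(aln), 1:4)

  writeLines(c(">a", "ACGT", ">b", "ACGTA"), fa)
  expect_error(readAlignment(fa), class = "porpopgen_shape_error")

  writeLines(c(">a", "ACXT"), fa)
  expect_error(readAlignment(fa), "non-IUPAC.*'X'.*'a'.*column 3")

  writeLines(character(), fa)
  expect_error(readAlignment(fa), class = "porpopgen_input_error")
})

test_that("alignment round-trips through FASTA losslessly", {
  set.seed(1)
  aln <- randomAln(5, 40, pGap = 0.05)
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeAlignment(aln, fa)
  back <- readAlignment(fa)
  expect_identical(as.character(alignmentSeqs(back)),
                   as.character(alignmentSeqs(aln)))
})

test_that("masking removes columns and preserves coordinate provenance", {
  aln <- makeAln(c(a = "ACGTACGTAC", b = "ACGTACGTAA"))
  expect_identical(applyMask(aln, IRanges::IRanges()), aln)

  masked <- applyMask(aln, maskIntervals(3, 5))
  expect_equal(alignmentWidth(masked), 7L)
  expect_equal(columnMap(masked), c(1L, 2L, 6L, 7L, 8L, 9L, 10L))
  # original untouched
  expect_equal(alignmentWidth(aln), 10L)

  expect_error(applyMask(aln, maskIntervals(8, 12)),
               class = "porpopgen_range_error")

  # inclusive vs half-open end convention
  expect_equal(sum(IRanges::width(maskIntervals(15508, 15734))), 227L)
  expect_equal(sum(IRanges::width(maskIntervals(15508, 15734,
                                                inclusive = FALSE))), 226L)
})

test_that("disjoint masks commute", {
  set.seed(2)
  aln <- randomAln(4, 30)
  m1 <- maskIntervals(3, 6)
  m2 <- maskIntervals(c(11, 25), c(14, 27))
  ab <- applyMask(applyMask(aln, m1), m2)
  ba <- applyMask(applyMask(aln, m2), m1)
  expect_identical(as.character(alignmentSeqs(ab)),
                   as.character(alignmentSeqs(ba)))
  expect_identical(columnMap(ab), columnMap(ba))
})

test_that("cds_concat handles strand, overlap duplication and frames", {
  # genes A (1-9, +) and B (7-12, -): concat length 15, overlap 7-9 twice
  aln <- makeAln(c(s1 = "ATGAAACCCGGG", s2 = "ATGAAACCCGGG"))
  ann <- twoGeneAnnotation()
  cds <- extractPartition(aln, ann, "cds_concat")
  expect_equal(alignmentWidth(cds), 15L)
  s <- as.character(alignmentSeqs(cds)[["s1"]])
  expect_equal(substr(s, 1, 9), "ATGAAACCC")           # A verbatim
  expect_equal(substr(s, 10, 15), "CCCGGG")            # revcomp of CCCGGG
  # B's columns reverse-complemented: recover original by reverse
  # complementing the block
  bBlock <- substr(s, 10, 15)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", bBlock), "")[[1]]),
              collapse = "")
  expect_equal(rc, substr("ATGAAACCCGGG", 7, 12))
  # overlap columns appear twice in the provenance map
  expect_equal(sum(columnMap(cds) %in% 7:9), 6L)

  # two non-overlapping plus-strand 6-bp CDS: concat equals slices
  ann2 <- geneAnnotation(c("x", "y"), c(1, 7), c(6, 12), c("+", "+"),
                         c("CDS", "CDS"))
  cds2 <- extractPartition(aln, ann2, "cds_concat")
  expect_equal(as.character(alignmentSeqs(cds2)[["s1"]]), "ATGAAACCCGGG")

  # incomplete terminal codon dropped with a warning
  ann3 <- geneAnnotation("z", 1, 8, "+", "CDS")
  expect_warning(cds3 <- extractPartition(aln, ann3, "cds_concat"),
                 "incomplete terminal codon")
  expect_equal(alignmentWidth(cds3), 6L)
})

test_that("partition lengths account for every column exactly", {
  set.seed(3)
  synth <- suppressWarnings(synthMitogenomeSet(
    groups = data.frame(species = "Pp", lineage = "A", n = 4, theta1 = 5),
    genomeLength = 16302L, seed = 7))
  aln <- synth$alignment; ann <- synth$ann
  kl <- S4Vectors::mcols(ann)$klass
  st <- GenomicRanges::start(ann); en <- GenomicRanges::end(ann)
  cds <- extractPartition(aln, ann, "cds_concat")
  nc <- extractPartition(aln, ann, "noncoding")
  # concatenated CDS length = sum of gene lengths (overlap duplicated),
  # exceeding the union by the 17-bp overlap
  expect_equal(alignmentWidth(cds), sum((en - st + 1)[kl == "CDS"]))
  union <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(st[kl == "CDS"], en[kl == "CDS"]))))
  expect_equal(alignmentWidth(cds) - union, 17L)
  # noncoding + union of all annotated features covers the genome
  feat <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(
    st[kl %in% c("CDS", "tRNA", "rRNA", "origin")],
    en[kl %in% c("CDS", "tRNA", "rRNA", "origin")]))))
  expect_equal(alignmentWidth(nc) + feat, 16302L)
  expect_identical(extractPartition(aln, ann, "whole"), aln)
})

test_that("minus-strand extraction is invertible", {
  set.seed(4)
  aln <- randomAln(3, 12)
  ann <- geneAnnotation("m", 4, 12, "-", "CDS")
  cds <- extractPartition(aln, ann, "cds_concat")
  m <- do.call(rbind, strsplit(as.character(alignmentSeqs(cds)), ""))
  rc <- t(apply(m, 1L, function(x)
    rev(chartr("ACGT", "TGCA", x))))
  orig <- do.call(rbind, strsplit(as.character(alignmentSeqs(aln)), ""))
  expect_equal(unname(rc), unname(orig[, 4:12]))
})

test_that("annotation and lineage I/O validate and round-trip", {
  ann <- twoGeneAnnotation()
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeAnnotation(ann, gff)
  back <- readAnnotation(gff)
  expect_equal(S4Vectors::mcols(back)$name, c("A", "B"))
  expect_equal(GenomicRanges::start(back), c(1L, 7L))
  expect_equal(as.character(GenomicRanges::strand(back)), c("+", "-"))

  expect_error(geneAnnotation(c("A", "A"), c(1, 5), c(3, 9), c("+", "+"),
                              c("CDS", "CDS")),
               "duplicate feature name")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tspecies\tlineage",
               paste0("v", 1:12, "\tvaquita\tV", collapse = "\n")), tsv)
  lt <- readLineageTable(tsv)
  expect_equal(nrow(lt), 12L)
  expect_equal(unique(lt$lineage), "V")

  writeLines(c("sample_id\tspecies\tlineage", "a\tx\tL1", "a\tx\tL1"), tsv)
  expect_error(readLineageTable(tsv), "duplicate sample_id")

  file.create(tsv2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_error(readLineageTable(tsv2), class = "porpopgen_input_error")

  aln <- makeAln(c(a = "ACGT", b = "ACGA"))
  # both directions of mismatch are reported
  expect_warning(
    expect_warning(validateLineages(data.frame(sample_id = c("a", "zz"),
                                               species = "x",
                                               lineage = "L"), aln),
                   "absent from alignment"),
    "absent from lineage table")
})

test_that("BED masks convert from 0-based half-open coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t2\t5\trepeat", bed)
  m <- readMask(bed)
  expect_equal(IRanges::start(m), 3L)
  expect_equal(IRanges::end(m), 5L)
})
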