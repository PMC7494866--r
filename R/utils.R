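# Internal helpers shared across modules.

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

COMPLEMENT_FROM <- "ACGTRYSWKMBDHVN-"
COMPLEMENT_TO   <- "TGCAYRSWMKVHDBN-"

stopInput <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("porpopgen_input_error", "error")))
}

stopRange <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("porpopgen_range_error", "error")))
}

stopShape <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("porpopgen_shape_error", "error")))
}

stopDegenerate <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("porpopgen_degenerate_error", "error")))
}

# Character matrix view of an alignment (rows = sequences, columns = sites).
alignmentMatrix <- function(aln) {
  m <- as.matrix(alignmentSeqs(aln))
  rownames(m) <- sampleIds(aln)
  m
}

# Integer coding: A=1 C=2 G=3 T=4, anything else (gap/N/ambiguity) NA.
# Downstream statistics treat NA as missing under complete deletion.
baseCodeMatrix <- function(aln) {
  m <- alignmentMatrix(aln)
  codes <- match(m, c("A", "C", "G", "T"))
  dim(codes) <- dim(m)
  rownames(codes) <- rownames(m)
  codes
}

# Columns usable under complete deletion: every state in {A,C,G,T}.
usableColumns <- function(codes) !apply(is.na(codes), 2L, any)

reverseComplementChars <- function(x) {
  rev(strsplit(chartr(COMPLEMENT_FROM, COMPLEMENT_TO,
                      paste(rev(x), collapse = "")), "")[[1]])
}

revcompString <- function(s) {
  chartr(COMPLEMENT_FROM, COMPLEMENT_TO,
         vapply(strsplit(s, ""), function(ch) paste(rev(ch), collapse = ""),
                ""))
}

# a1 = sum_{i=1}^{n-1} 1/i and a2 = sum 1/i^2 (Watterson/Tajima coefficients)
harmonicA1 <- function(n) sum(1 / seq_len(n - 1L))
harmonicA2 <- function(n) sum(1 / seq_len(n - 1L)^2)

# Construct a MitoAlignment from a character vector of sequences.
newAlignment <- function(seqs, ids = NULL, columnMap = NULL) {
  if (is.null(ids)) ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  if (is.null(columnMap)) {
    columnMap <- if (length(dss)) seq_len(Biostrings::width(dss)[1L])
                 else integer()
  }
  methods::new("MitoAlignment", seqs = dss, columnMap = as.integer(columnMap))
}
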