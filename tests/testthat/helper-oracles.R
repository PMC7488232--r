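# Independent oracles used to cross-check the implementation.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s),
                     "")[[1]]), collapse = "")
}

# per-position double-strand brute-force matcher; subject N never matches
brute_scan <- function(sequence, recognition) {
  seqc <- strsplit(sequence, "")[[1]]
  pats <- unique(c(recognition, revcomp_chr(recognition)))
  w <- nchar(recognition)
  n <- nchar(sequence)
  if (n < w) return(integer(0))
  hits <- integer(0)
  for (p in seq_len(n - w + 1)) {
    win <- seqc[p:(p + w - 1)]
    for (pat in pats) {
      patc <- strsplit(pat, "")[[1]]
      ok <- TRUE
      for (k in seq_len(w)) {
        if (!(win[k] %in% IUPAC_SETS[[patc[k]]])) { ok <- FALSE; break }
      }
      if (ok) { hits <- c(hits, p); break }
    }
  }
  hits
}

random_dna <- function(n, p_n = 0) {
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (p_n > 0) b[runif(n) < p_n] <- "N"
  paste(b, collapse = "")
}

# translate with seqinr (independent of Biostrings) and report per-position
# amino-acid differences between two in-frame coding sequences
oracle_aa_diff <- function(cds_ref, cds_alt) {
  tr <- function(s) paste(seqinr::translate(strsplit(tolower(s), "")[[1]]),
                          collapse = "")
  a <- tr(cds_ref); b <- tr(cds_alt)
  stopifnot(nchar(a) == nchar(b))
  which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# reverse complement plain ACGT
rc <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

# build a simple two-exon plus-strand gene with a complete CDS for tests
simple_gene <- function() {
  seq1 <- paste0(strrep("T", 100), "ATGTCTCGACTTGGG",
                 "GT", strrep("C", 50), "AG", "TACTAA", strrep("G", 100))
  g <- genome(c(c1 = seq1))
  m <- gene_model("geneA", "txA", "c1", "+",
                  exons = rbind(c(101, 115), c(170, 175)),
                  cds   = rbind(c(101, 115), c(170, 175)))
  list(genome = g, model = m, seq = seq1)
}
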