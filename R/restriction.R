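# IUPAC-aware restriction-site scanning, in-silico digestion, and
# genome-wide site statistics for RADseq enzyme selection.

#' Construct a restriction enzyme
#'
#' @param name enzyme name.
#' @param recognition IUPAC recognition motif (length >= 4).
#' @param cut_offset 0-based offset of the top-strand cut within the
#'   site, or `NA` for unknown (mid-site is then assumed by
#'   [digest_fragments()]).
#' @param cpg logical; does the motif contain a CpG dinucleotide (such
#'   enzymes are methylation-sensitive in vertebrate genomes and
#'   under-cut relative to base composition).
#' @return an object of class `enzyme`; `is_palindromic` is derived as
#'   equality of the motif with its IUPAC reverse complement.
#' @export
enzyme <- function(name, recognition, cut_offset = NA_integer_, cpg = NA) {
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4L) stop("recognition motif shorter than 4")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", recognition))
    stop("recognition motif contains non-IUPAC characters")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(recognition)))
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset),
                 is_palindromic = identical(rc, recognition),
                 cpg = cpg),
            class = "enzyme")
}

#' @exportS3Method base::print
print.enzyme <- function(x, ...) {
  cat(sprintf("enzyme %s: %s%s%s\n", x$name, x$recognition,
              if (x$is_palindromic) " (palindromic)" else "",
              if (!is.na(x$cut_offset)) paste0(", cut at +", x$cut_offset)
              else ""))
  invisible(x)
}

# The built-in panel: the 30 enzymes of the genome-wide site survey plus
# the enzymes used by the diagnostic candidate-gene markers. Recognition
# sequences and top-strand cut offsets are the standard REBASE ones.
.builtin_enzyme_rows <- function() {
  t4 <- c(
    "ApaI,GGGCCC,5,TRUE",    "AscI,GGCGCGCC,2,TRUE",
    "AvrII,CCTAGG,1,FALSE",  "BamHI,GGATCC,1,FALSE",
    "BspQI,GCTCTTC,NA,FALSE","BssHII,GCGCGC,1,TRUE",
    "DraI,TTTAAA,3,FALSE",   "EagI,CGGCCG,1,TRUE",
    "EcoRI,GAATTC,1,FALSE",  "FseI,GGCCGGCC,6,TRUE",
    "HindIII,AAGCTT,1,FALSE","NaeI,GCCGGC,3,TRUE",
    "NarI,GGCGCC,2,TRUE",    "NheI,GCTAGC,1,FALSE",
    "NotI,GCGGCCGC,2,TRUE",  "PacI,TTAATTAA,5,FALSE",
    "PmeI,GTTTAAAC,4,FALSE", "RsrII,CGGWCCG,2,TRUE",
    "SacI,GAGCTC,5,FALSE",   "SacII,CCGCGG,4,TRUE",
    "SalI,GTCGAC,1,TRUE",    "SbfI,CCTGCAGG,6,FALSE",
    "SgrAI,CRCCGGYG,2,TRUE", "SmaI,CCCGGG,3,TRUE",
    "SpeI,ACTAGT,1,FALSE",   "SphI,GCATGC,5,FALSE",
    "SspI,AATATT,3,FALSE",   "SwaI,ATTTAAAT,4,FALSE",
    "XbaI,TCTAGA,1,FALSE",   "XhoI,CTCGAG,1,TRUE")
  t5 <- c(
    "StuI,AGGCCT,3,FALSE",   "MspI,CCGG,1,TRUE",
    "KpnI,GGTACC,5,FALSE",   "AciI,CCGC,1,TRUE")
  read.table(text = paste(c(t4, t5), collapse = "\n"), sep = ",",
             col.names = c("name", "recognition", "cut_offset", "cpg"),
             na.strings = "NA", stringsAsFactors = FALSE)
}

#' The built-in enzyme catalog
#'
#' The 30-enzyme RADseq survey panel plus the marker enzymes (StuI, MspI,
#' KpnI, AciI), as a named list of [enzyme()] objects.
#'
#' @param names optional character vector to subset the catalog.
#' @return named list of `enzyme` objects.
#' @export
enzyme_catalog <- function(names = NULL) {
  rows <- .builtin_enzyme_rows()
  if (!is.null(names)) {
    miss <- setdiff(names, rows$name)
    if (length(miss)) stop("unknown enzyme(s): ", paste(miss, collapse = ", "))
    rows <- rows[match(names, rows$name), , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(rows)), function(i)
    enzyme(rows$name[i], rows$recognition[i], rows$cut_offset[i],
           rows$cpg[i]))
  setNames(out, rows$name)
}

#' Read a user enzyme table (TSV: name, recognition, cut_offset, cpg)
#' @param path path to a tab-separated table with a header row.
#' @return named list of [enzyme()] objects.
#' @export
read_enzyme_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "recognition")
  if (!all(need %in% names(d))) stop("enzyme TSV needs columns: name, recognition")
  if (is.null(d$cut_offset)) d$cut_offset <- NA_integer_
  if (is.null(d$cpg)) d$cpg <- NA
  out <- lapply(seq_len(nrow(d)), function(i)
    enzyme(d$name[i], d$recognition[i], d$cut_offset[i], d$cpg[i]))
  setNames(out, d$name)
}

#' Scan a sequence for recognition sites
#'
#' Reports every 1-based start position whose window matches the motif
#' under IUPAC expansion on the forward strand, or whose window is
#' matched there by the motif's reverse complement (a site is cuttable
#' regardless of the strand it is written on). Palindromic motifs are
#' reported once per position. Windows containing N never match:
#' assembly gaps must not inflate site counts.
#'
#' @param sequence a nucleotide string over A/C/G/T/N.
#' @param enz an [enzyme()].
#' @return sorted integer vector of 1-based site start positions.
#' @export
scan_sites <- function(sequence, enz) {
  if (nchar(sequence) < nchar(enz$recognition)) return(integer(0L))
  subj <- Biostrings::DNAString(sequence)
  pat <- Biostrings::DNAString(enz$recognition)
  # fixed = "subject": motif ambiguity codes expand, subject letters are
  # literal, so N in the sequence matches nothing.
  hits <- Biostrings::start(
    Biostrings::matchPattern(pat, subj, fixed = "subject"))
  if (!enz$is_palindromic) {
    rc <- Biostrings::reverseComplement(pat)
    hits <- c(hits, Biostrings::start(
      Biostrings::matchPattern(rc, subj, fixed = "subject")))
  }
  sort(unique(as.integer(hits)))
}

#' Digest a sequence with one or more enzymes
#'
#' Cut positions are site start + cut offset (mid-site when the catalog
#' has no offset). The fragment multiset always partitions the input:
#' an uncut sequence yields a single full-length fragment.
#'
#' @param sequence nucleotide string.
#' @param enzymes an [enzyme()] or list of them.
#' @return object of class `fragment_pattern`: list with
#'   `fragment_lengths` (sorted integer vector), `cut_positions`, and
#'   `source_length`.
#' @export
digest_fragments <- function(sequence, enzymes) {
  if (inherits(enzymes, "enzyme")) enzymes <- list(enzymes)
  if (length(enzymes) == 0L) stop("at least one enzyme required")
  n <- nchar(sequence)
  cuts <- integer(0L)
  for (enz in enzymes) {
    off <- if (is.na(enz$cut_offset)) nchar(enz$recognition) %/% 2L
           else enz$cut_offset
    cuts <- c(cuts, scan_sites(sequence, enz) + off - 1L)
  }
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < n]))  # cut after base i
  bounds <- c(0L, cuts, n)
  structure(list(fragment_lengths = sort(diff(bounds)),
                 cut_positions = cuts, source_length = n),
            class = "fragment_pattern")
}

#' @exportS3Method base::print
print.fragment_pattern <- function(x, ...) {
  cat("fragment_pattern:", length(x$fragment_lengths), "fragment(s) of",
      x$source_length, "bp:", paste(x$fragment_lengths, collapse = ", "),
      "\n")
  invisible(x)
}

#' Genome-wide recognition-site statistics for one enzyme
#'
#' Counts recognition sites C over all contigs and derives the average
#' fragment size L = round(G / C) (G the assembly length) and the RAD
#' marker yield R = 2C (each site is sequenced from both flanks).
#'
#' @param g a [genome()].
#' @param enz an [enzyme()].
#' @return object of class `site_stats`: list with `enzyme_name`,
#'   `site_count`, `avg_fragment` (NA when the count is zero),
#'   `rad_markers`, `genome_length`.
#' @export
genome_site_stats <- function(g, enz) {
  if (g$total_length == 0L) stop("empty genome")
  C <- sum(vapply(g$contigs, function(s) length(scan_sites(s, enz)),
                  integer(1L)))
  structure(list(enzyme_name = enz$name, site_count = C,
                 avg_fragment = if (C > 0L) round(g$total_length / C)
                                else NA_real_,
                 rad_markers = 2L * C, genome_length = g$total_length),
            class = "site_stats")
}

#' @exportS3Method base::print
print.site_stats <- function(x, ...) {
  cat(sprintf("%s: %s sites, avg fragment %s bp, %s RAD markers (G = %s)\n",
              x$enzyme_name, format(x$site_count, big.mark = ","),
              if (is.na(x$avg_fragment)) "NA"
              else format(x$avg_fragment, big.mark = ","),
              format(x$rad_markers, big.mark = ","),
              format(x$genome_length, big.mark = ",")))
  invisible(x)
}

#' Rank enzymes by closeness to a target marker spacing
#'
#' For RADseq planning: enzymes are ordered by |avg fragment - target|,
#' ties broken alphabetically. Enzymes with zero sites sort last.
#'
#' @param g a [genome()].
#' @param enzymes list of [enzyme()] objects.
#' @param target_marker_spacing desired average fragment size in bp.
#' @return a `data.frame` (one row per enzyme, best first) with columns
#'   `enzyme`, `site_count`, `avg_fragment`, `rad_markers`, `distance`.
#' @export
rank_enzymes <- function(g, enzymes, target_marker_spacing) {
  if (length(enzymes) == 0L) stop("empty enzyme list")
  if (target_marker_spacing <= 0) stop("target spacing must be positive")
  stats <- lapply(enzymes, function(e) genome_site_stats(g, e))
  d <- data.frame(
    enzyme = vapply(stats, `[[`, character(1L), "enzyme_name"),
    site_count = vapply(stats, `[[`, numeric(1L), "site_count"),
    avg_fragment = vapply(stats, `[[`, numeric(1L), "avg_fragment"),
    rad_markers = vapply(stats, `[[`, numeric(1L), "rad_markers"),
    stringsAsFactors = FALSE)
  d$distance <- abs(d$avg_fragment - target_marker_spacing)
  ord <- order(is.na(d$distance), d$distance, d$enzyme)
  d <- d[ord, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Export site positions as BED
#'
#' @param g a [genome()].
#' @param enz an [enzyme()].
#' @param path output path; BED is 0-based half-open by convention, the
#'   only place this package emits that frame.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(g, enz, path) {
  lines <- character(0L)
  w <- nchar(enz$recognition)
  for (nm in names(g$contigs)) {
    p <- scan_sites(g$contigs[[nm]], enz)
    if (length(p))
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s", nm, p - 1L, p + w - 1L,
                                enz$name))
  }
  writeLines(lines, path)
  invisible(path)
}
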