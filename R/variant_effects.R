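# Simplified variant-consequence annotation: genomic-region categories
# (exon/intron/UTR/splice/flank/intergenic) per overlapping transcript,
# and coding effects by translating the spliced CDS of both haplotypes.

.REGION_CATEGORIES <- c("exon", "intron", "utr5", "utr3",
                        "splice_acceptor", "splice_donor", "splice_region",
                        "upstream5kb", "downstream5kb", "intergenic")

.overlaps <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2

#' Classify the genomic region(s) a variant falls in
#'
#' Per overlapping transcript: exon/intron by containment; 5'/3' UTR by
#' exonic position relative to the CDS span (strand-aware); splice donor/
#' acceptor are the 2 intronic bases abutting each exon boundary; splice
#' region covers intronic bases 3-8 and exonic bases 1-3 from a boundary
#' (the convention of mainstream annotation tools, configurable);
#' upstream/downstream are within `flank` bp of the transcript span,
#' strand-aware. A variant overlapping nothing is `intergenic` — the
#' category set is exhaustive, every variant receives at least one
#' annotation, and one variant may receive several across transcripts.
#'
#' @param variant one-row `variant_table` (or list with `contig`, `pos`,
#'   `ref`).
#' @param gene_models list of [gene_model()] objects.
#' @param flank flank width for upstream/downstream in bp (default 5000).
#' @param splice_region_intron,splice_region_exon extents of the splice
#'   region into intron and exon (defaults 3:8 and 1:3 bases from the
#'   boundary).
#' @return `data.frame` with columns `category`, `gene_id`,
#'   `transcript_id` (`NA` for intergenic).
#' @export
classify_region <- function(variant, gene_models, flank = 5000L,
                            splice_region_intron = c(3L, 8L),
                            splice_region_exon = c(1L, 3L)) {
  v <- as.list(variant)
  vs <- as.integer(v$pos)
  ve <- vs + nchar(v$ref) - 1L
  rows <- list()
  add <- function(cat, gid, tid)
    rows[[length(rows) + 1L]] <<- data.frame(
      category = cat, gene_id = gid, transcript_id = tid,
      stringsAsFactors = FALSE)

  for (m in gene_models) {
    if (m$contig != v$contig) next
    span <- c(min(m$exons[, 1L]), max(m$exons[, 2L]))
    if (.overlaps(vs, ve, span[1L], span[2L])) {
      ex <- m$exons
      in_exon <- any(.overlaps(vs, ve, ex[, 1L], ex[, 2L]))
      if (in_exon) {
        add("exon", m$gene_id, m$transcript_id)
        if (nrow(m$cds) > 0L) {
          cs <- min(m$cds[, 1L]); ce <- max(m$cds[, 2L])
          # exonic portion strictly outside the CDS span is UTR
          left <- vs < cs; right <- ve > ce
          if (left)  add(if (m$strand == "+") "utr5" else "utr3",
                         m$gene_id, m$transcript_id)
          if (right) add(if (m$strand == "+") "utr3" else "utr5",
                         m$gene_id, m$transcript_id)
        }
      }
      if (nrow(ex) > 1L) {
        for (i in seq_len(nrow(ex) - 1L)) {
          is_ <- ex[i, 2L] + 1L; ie <- ex[i + 1L, 1L] - 1L
          if (ie < is_) next
          if (.overlaps(vs, ve, is_, ie))
            add("intron", m$gene_id, m$transcript_id)
          # left end of intron in genome order: donor on +, acceptor on -
          l2 <- c(is_, min(is_ + 1L, ie))
          r2 <- c(max(ie - 1L, is_), ie)
          if (.overlaps(vs, ve, l2[1L], l2[2L]))
            add(if (m$strand == "+") "splice_donor" else "splice_acceptor",
                m$gene_id, m$transcript_id)
          if (.overlaps(vs, ve, r2[1L], r2[2L]))
            add(if (m$strand == "+") "splice_acceptor" else "splice_donor",
                m$gene_id, m$transcript_id)
          # splice region: intronic 3-8 from each boundary
          sri <- splice_region_intron
          li <- c(is_ + sri[1L] - 1L, min(is_ + sri[2L] - 1L, ie))
          ri <- c(max(ie - sri[2L] + 1L, is_), ie - sri[1L] + 1L)
          hit_sr <- (li[1L] <= li[2L] && .overlaps(vs, ve, li[1L], li[2L])) ||
                    (ri[1L] <= ri[2L] && .overlaps(vs, ve, ri[1L], ri[2L]))
          # splice region: exonic 1-3 from each internal boundary
          sre <- splice_region_exon
          le <- c(max(ex[i, 2L] - sre[2L] + 1L, ex[i, 1L]), ex[i, 2L])
          re <- c(ex[i + 1L, 1L], min(ex[i + 1L, 1L] + sre[2L] - 1L,
                                      ex[i + 1L, 2L]))
          hit_sr <- hit_sr || .overlaps(vs, ve, le[1L], le[2L]) ||
                    .overlaps(vs, ve, re[1L], re[2L])
          if (hit_sr) add("splice_region", m$gene_id, m$transcript_id)
        }
      }
    } else if (.overlaps(vs, ve, span[1L] - flank, span[2L] + flank)) {
      before <- ve < span[1L]
      up <- (m$strand == "+") == before
      add(if (up) "upstream5kb" else "downstream5kb",
          m$gene_id, m$transcript_id)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(category = "intergenic", gene_id = NA_character_,
                      transcript_id = NA_character_,
                      stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

# Spliced CDS of a transcript on the coding strand.
.cds_sequence <- function(m, g) {
  s <- contig_seq(g, m$contig)
  parts <- vapply(seq_len(nrow(m$cds)), function(i)
    substr(s, m$cds[i, 1L], m$cds[i, 2L]), character(1L))
  cds <- paste0(parts, collapse = "")
  if (m$strand == "-")
    cds <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds)))
  cds
}

# genome position -> 1-based offset in the spliced CDS (coding strand)
.cds_offset <- function(m, pos) {
  lens <- m$cds[, 2L] - m$cds[, 1L] + 1L
  cum <- cumsum(lens)
  i <- which(m$cds[, 1L] <= pos & pos <= m$cds[, 2L])
  if (length(i) == 0L) return(NA_integer_)
  off_plus <- (if (i > 1L) cum[i - 1L] else 0L) + (pos - m$cds[i, 1L] + 1L)
  unname(if (m$strand == "+") off_plus else sum(lens) - off_plus + 1L)
}

.translate <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) return("")
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n)), no.init.codon = TRUE)))
}

#' Coding consequence of a variant on one transcript
#'
#' Splices the CDS, applies the variant, translates both haplotypes with
#' the standard genetic code (reverse-complemented for minus-strand
#' transcripts), and classifies: length-preserving SNPs as silent /
#' missense / nonsense / stop_lost / start_lost by codon comparison;
#' indels as in-frame or frameshift by length modulo 3.
#'
#' @param variant one-row `variant_table` (or equivalent list). The
#'   variant's reference span must lie within a single CDS interval of
#'   the transcript.
#' @param transcript a [gene_model()].
#' @param g a [genome()].
#' @return an object of class `coding_effect` (fields `transcript_id`,
#'   `effect`, `ref_aa`, `alt_aa`, `aa_position`), or `NULL` when the
#'   variant does not overlap the transcript's CDS, or `NA` (flagged,
#'   with a warning) for incomplete CDS models.
#' @export
coding_effect <- function(variant, transcript, g) {
  v <- as.list(variant)
  m <- transcript
  if (nrow(m$cds) == 0L) return(NULL)
  vs <- as.integer(v$pos); ve <- vs + nchar(v$ref) - 1L
  hit <- which(m$cds[, 1L] <= vs & ve <= m$cds[, 2L])
  if (length(hit) == 0L) {
    if (any(.overlaps(vs, ve, m$cds[, 1L], m$cds[, 2L])))
      warning("variant straddles a CDS boundary; skipped")
    return(NULL)
  }
  cds_ref <- .cds_sequence(m, g)
  if (nchar(cds_ref) %% 3L != 0L) {
    warning("incomplete CDS (length not divisible by 3) in ",
            m$transcript_id, "; skipped")
    return(structure(NA, class = "incomplete_cds"))
  }
  ref <- v$ref; alt <- v$alt
  if (m$strand == "+") {
    off <- .cds_offset(m, vs)
  } else {
    off <- .cds_offset(m, ve)  # 5'-most coding-strand base of the span
    ref <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ref)))
    alt <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(alt)))
  }
  if (substr(cds_ref, off, off + nchar(ref) - 1L) != ref)
    stop("variant REF allele does not match the spliced CDS of ",
         m$transcript_id, " at offset ", off,
         " (is the variant validated against this genome?)")
  cds_alt <- paste0(substr(cds_ref, 1L, off - 1L), alt,
                    substr(cds_ref, off + nchar(ref), nchar(cds_ref)))
  dlen <- nchar(alt) - nchar(ref)
  prot_ref <- .translate(cds_ref)

  if (dlen != 0L) {
    eff <- if (dlen %% 3L != 0L) "frameshift"
           else if (dlen > 0L) "inframe_insertion" else "inframe_deletion"
    return(structure(list(transcript_id = m$transcript_id, effect = eff,
                          ref_aa = NA_character_, alt_aa = NA_character_,
                          aa_position = (off + 2L) %/% 3L),
                     class = "coding_effect"))
  }
  prot_alt <- .translate(cds_alt)
  aa_pos <- (off + 2L) %/% 3L
  ref_aa <- substr(prot_ref, aa_pos, aa_pos)
  alt_aa <- substr(prot_alt, aa_pos, aa_pos)
  eff <- if (ref_aa == alt_aa) "silent"
         else if (alt_aa == "*") "nonsense"
         else if (ref_aa == "*") "stop_lost"
         else if (aa_pos == 1L && ref_aa == "M") "start_lost"
         else "missense"
  structure(list(transcript_id = m$transcript_id, effect = eff,
                 ref_aa = ref_aa, alt_aa = alt_aa, aa_position = aa_pos),
            class = "coding_effect")
}

#' @exportS3Method base::print
print.coding_effect <- function(x, ...) {
  cat(sprintf("coding_effect %s: %s%s\n", x$transcript_id, x$effect,
              if (!is.na(x$ref_aa))
                sprintf(" (%s%d%s)", x$ref_aa, x$aa_position, x$alt_aa)
              else ""))
  invisible(x)
}

#' Summarize variant annotations and coding effects
#'
#' Tabulates region-category counts with multiplicity (one variant may
#' carry several annotations), per-gene rollups, and the variant rate
#' (covered bases per variant).
#'
#' @param variants a `variant_table`.
#' @param gene_models list of [gene_model()] objects.
#' @param g a [genome()] (needed for coding effects).
#' @param covered_length number of reference bases with adequate
#'   coverage backing the variant calls; the denominator of the variant
#'   rate.
#' @param flank flank width passed to [classify_region()].
#' @return an object of class `effect_summary`: list with
#'   `region_counts` (named vector over all categories),
#'   `effect_counts` (named vector over coding-effect classes),
#'   `n_genes_with_cds_snp`, `n_genes_nonsynonymous` (genes with a
#'   missense or nonsense SNP), and `variant_rate_bp` =
#'   `round(covered_length / n variants)` (`NA` when there are no
#'   variants).
#' @export
summarize_effects <- function(variants, gene_models, g, covered_length,
                              flank = 5000L) {
  if (covered_length <= 0) stop("covered_length must be positive")
  region_counts <- setNames(integer(length(.REGION_CATEGORIES)),
                            .REGION_CATEGORIES)
  eff_classes <- c("silent", "missense", "nonsense", "inframe_deletion",
                   "inframe_insertion", "frameshift", "stop_lost",
                   "start_lost")
  effect_counts <- setNames(integer(length(eff_classes)), eff_classes)
  genes_cds_snp <- character(0L)
  genes_nonsyn <- character(0L)
  by_tid <- setNames(gene_models,
                     vapply(gene_models, `[[`, character(1L),
                            "transcript_id"))
  for (i in seq_len(nrow(variants))) {
    vr <- variants[i, , drop = FALSE]
    ann <- classify_region(vr, gene_models, flank = flank)
    tab <- table(ann$category)
    region_counts[names(tab)] <- region_counts[names(tab)] + as.integer(tab)
    for (tid in unique(ann$transcript_id[!is.na(ann$transcript_id)])) {
      m <- by_tid[[tid]]
      ce <- suppressWarnings(coding_effect(vr, m, g))
      if (is.null(ce) || inherits(ce, "incomplete_cds")) next
      effect_counts[ce$effect] <- effect_counts[ce$effect] + 1L
      if (vr$kind == "SNP")
        genes_cds_snp <- union(genes_cds_snp, m$gene_id)
      if (ce$effect %in% c("missense", "nonsense"))
        genes_nonsyn <- union(genes_nonsyn, m$gene_id)
    }
  }
  structure(list(region_counts = region_counts,
                 effect_counts = effect_counts,
                 n_genes_with_cds_snp = length(genes_cds_snp),
                 n_genes_nonsynonymous = length(genes_nonsyn),
                 n_variants = nrow(variants),
                 covered_length = covered_length,
                 variant_rate_bp = if (nrow(variants) > 0L)
                   round(covered_length / nrow(variants)) else NA_real_),
            class = "effect_summary")
}

#' @exportS3Method base::print
print.effect_summary <- function(x, ...) {
  cat("effect_summary:", x$n_variants, "variant(s), rate one per",
      ifelse(is.na(x$variant_rate_bp), "NA", x$variant_rate_bp), "bp\n")
  nz <- x$region_counts[x$region_counts > 0L]
  if (length(nz)) {
    cat("  regions: ")
    cat(paste(names(nz), nz, sep = "=", collapse = ", "), "\n")
  }
  nz <- x$effect_counts[x$effect_counts > 0L]
  if (length(nz)) {
    cat("  coding:  ")
    cat(paste(names(nz), nz, sep = "=", collapse = ", "), "\n")
  }
  cat("  genes with CDS SNP:", x$n_genes_with_cds_snp,
      "| genes with nonsynonymous SNP:", x$n_genes_nonsynonymous, "\n")
  invisible(x)
}
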