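# Genome / variant / gene-model containers and standard-format IO.
# External coordinates are 1-based inclusive throughout; no other frame is
# ever exposed.

#' Construct a genome object
#'
#' A genome is an ordered set of named contigs of uppercase A/C/G/T/N
#' sequence. Non-ACGTN characters (IUPAC ambiguity codes other than N)
#' are mapped to N with a warning: the site scanner requires deterministic
#' base identity, and an ambiguous base must not create a recognition site.
#'
#' @param contigs named character vector of nucleotide sequences.
#' @return An object of class `genome` with elements `contigs` (named
#'   uppercase character vector) and `total_length` (sum of contig
#'   lengths, the assembly length G used by fragment-size statistics).
#' @export
genome <- function(contigs) {
  nm <- names(contigs)
  if (is.null(nm) || any(!nzchar(nm))) stop("contig names must be non-empty")
  if (anyDuplicated(nm)) stop("duplicate contig name: ", nm[duplicated(nm)][1L])
  contigs <- toupper(as.character(contigs))
  bad <- vapply(contigs, function(s) {
    sum(charToRaw(chartr("ACGTN", "     ", s)) != charToRaw(" "))
  }, integer(1L))
  if (sum(bad) > 0L) {
    warning(sum(bad), " non-ACGTN characters mapped to N")
    contigs <- vapply(contigs, function(s) {
      s <- chartr("RYSWKMBDHV", "NNNNNNNNNN", s)
      gsub("[^ACGTN]", "N", s)
    }, character(1L))
  }
  names(contigs) <- nm
  structure(
    list(contigs = contigs, total_length = sum(nchar(contigs))),
    class = "genome"
  )
}

#' @exportS3Method base::print
print.genome <- function(x, ...) {
  cat("genome:", length(x$contigs), "contig(s),",
      format(x$total_length, big.mark = ","), "bp\n")
  invisible(x)
}

#' Extract a contig sequence
#' @param g a [genome()].
#' @param contig contig name.
#' @return the contig sequence as a single string.
#' @export
contig_seq <- function(g, contig) {
  if (!contig %in% names(g$contigs)) stop("unknown contig: ", contig)
  g$contigs[[contig]]
}

#' Read a multi-record FASTA file into a genome
#'
#' @param path path to a FASTA file.
#' @return a [genome()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate contig name in FASTA: ",
                              nm[duplicated(nm)][1L])
  genome(setNames(as.character(ss), nm))
}

#' Write a genome to FASTA
#' @param g a [genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path) {
  ss <- Biostrings::DNAStringSet(g$contigs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Construct a validated variant table
#'
#' Variants are anchored, biallelic edits between the reference ("BW")
#' and alternate ("PO") haplotype: `pos` is the 1-based position of the
#' first reference base, and indels carry the shared anchor base in both
#' alleles (VCF convention). `kind` is derived: SNP when both alleles are
#' single differing bases, insertion when the alternate allele is longer,
#' deletion when shorter.
#'
#' @param contig,pos,ref,alt parallel vectors describing each variant.
#' @param g optional [genome()]; when given, `ref` is checked against the
#'   genome sequence and mismatching records are rejected.
#' @return a `data.frame` of class `variant_table` with columns
#'   `contig`, `pos`, `ref`, `alt`, `kind`.
#' @export
variant_table <- function(contig, pos, ref, alt, g = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(grepl("N", ref)) || any(grepl("N", alt)))
    stop("variant alleles must not contain N")
  if (any(!grepl("^[ACGT]+$", ref)) || any(!grepl("^[ACGT]+$", alt)))
    stop("variant alleles must be ACGT strings")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  kind <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP",
          ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
  v <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                  ref = ref, alt = alt, kind = kind,
                  stringsAsFactors = FALSE)
  if (!is.null(g)) {
    obs <- vapply(seq_len(nrow(v)), function(i) {
      s <- contig_seq(g, v$contig[i])
      substr(s, v$pos[i], v$pos[i] + nchar(v$ref[i]) - 1L)
    }, character(1L))
    if (any(obs != v$ref))
      stop("REF mismatch at ", v$contig[which(obs != v$ref)[1L]], ":",
           v$pos[which(obs != v$ref)[1L]])
  }
  class(v) <- c("variant_table", "data.frame")
  v
}

#' Read a VCF file into a variant table
#'
#' Only the CHROM/POS/ID/REF/ALT columns are used. Records are validated
#' against the genome: multiallelic records and records whose REF allele
#' disagrees with the genome sequence are skipped and reported.
#'
#' @param path path to an uncompressed VCF.
#' @param g a [genome()] to validate against.
#' @return a `variant_table`; attribute `errors` holds a character vector
#'   describing every skipped record (length 0 when clean).
#' @export
read_vcf <- function(path, g) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  errors <- character(0L)
  keep <- rep(TRUE, nrow(fix))
  for (i in seq_len(nrow(fix))) {
    chrom <- fix$CHROM[i]; pos <- as.integer(fix$POS[i])
    ref <- toupper(fix$REF[i]); alt <- toupper(fix$ALT[i])
    rec <- paste0(chrom, ":", pos)
    if (grepl(",", alt)) {
      errors <- c(errors, paste0(rec, ": multiallelic record"))
      keep[i] <- FALSE; next
    }
    if (!chrom %in% names(g$contigs)) {
      errors <- c(errors, paste0(rec, ": unknown contig"))
      keep[i] <- FALSE; next
    }
    obs <- substr(contig_seq(g, chrom), pos, pos + nchar(ref) - 1L)
    if (obs != ref) {
      errors <- c(errors, paste0(rec, ": REF mismatch (", ref, " vs ", obs, ")"))
      keep[i] <- FALSE
    }
  }
  fix <- fix[keep, , drop = FALSE]
  vt <- variant_table(fix$CHROM, as.integer(fix$POS),
                      toupper(fix$REF), toupper(fix$ALT))
  attr(vt, "errors") <- errors
  vt
}

#' Write a variant table as a minimal VCF
#'
#' Emits an uncompressed VCF v4.2 with CHROM/POS/ID/REF/ALT columns
#' (QUAL/FILTER/INFO set to missing), the subset this pipeline consumes.
#'
#' @param v a `variant_table`.
#' @param path output path.
#' @param g optional [genome()]; adds contig header lines when given.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(v, path, g = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=spotmap")
  if (!is.null(g))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(g$contigs), nchar(g$contigs)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", v$contig, v$pos, v$ref, v$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Construct a gene model
#'
#' @param gene_id,transcript_id,contig,strand identifiers; `strand` is
#'   `"+"` or `"-"`.
#' @param exons,cds two-column matrices of 1-based inclusive
#'   `(start, end)` intervals in genome order. Every CDS interval must lie
#'   inside an exon; exons must be sorted and non-overlapping.
#' @param gene_symbol optional display symbol.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, contig, strand, exons,
                       cds = NULL, gene_symbol = gene_id) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 1L] > exons[, 2L])) stop("exon start > end")
  if (is.unsorted(exons[, 1L], strictly = TRUE) && nrow(exons) > 1L)
    stop("exons must be sorted by genome coordinate")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop("exons overlap")
  if (!strand %in% c("+", "-")) stop("strand must be + or -")
  if (!is.null(cds) && nrow(cds) > 0L) {
    cds <- matrix(as.integer(cds), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons[, 1L] <= cds[i, 1L] & cds[i, 2L] <= exons[, 2L])
    }, logical(1L))
    if (!all(inside)) stop("CDS interval outside exon in ", transcript_id)
  } else cds <- matrix(integer(0L), ncol = 2L,
                       dimnames = list(NULL, c("start", "end")))
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 contig = contig, strand = strand, exons = exons, cds = cds,
                 gene_symbol = gene_symbol),
            class = "gene_model")
}

#' @exportS3Method base::print
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s) %s:%d-%d [%s] %d exon(s), %d CDS segment(s)\n",
              x$transcript_id, x$gene_id, x$contig,
              min(x$exons[, 1L]), max(x$exons[, 2L]), x$strand,
              nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS features into one [gene_model()] per
#' transcript. Transcripts violating the model invariants (CDS outside an
#' exon, overlapping exons) are dropped and reported via the `errors`
#' attribute.
#'
#' @param path path to a GFF3 file.
#' @return a list of `gene_model` objects; attribute `errors` lists
#'   dropped transcripts with reasons.
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  errors <- character(0L)
  models <- list()
  for (i in seq_len(nrow(mrna))) {
    tid <- mrna$ID[i]
    gid <- if (!is.null(mrna$Parent[[i]]) && length(mrna$Parent[[i]]))
      as.character(mrna$Parent[[i]])[1L] else tid
    kids <- df[vapply(df$Parent, function(p) tid %in% as.character(p),
                      logical(1L)), , drop = FALSE]
    ex <- kids[kids$type == "exon", c("start", "end"), drop = FALSE]
    cd <- kids[kids$type == "CDS", c("start", "end"), drop = FALSE]
    ex <- as.matrix(ex[order(ex$start), , drop = FALSE])
    cd <- as.matrix(cd[order(cd$start), , drop = FALSE])
    m <- tryCatch(
      gene_model(gene_id = gid, transcript_id = tid,
                 contig = mrna$seqnames[i], strand = mrna$strand[i],
                 exons = ex, cds = cd,
                 gene_symbol = if (!is.null(mrna$gene_symbol))
                   mrna$gene_symbol[i] else gid),
      error = function(e) conditionMessage(e))
    if (is.character(m)) errors <- c(errors, paste0(tid, ": ", m))
    else models[[length(models) + 1L]] <- m
  }
  attr(models, "errors") <- errors
  models
}

#' Write gene models to GFF3
#' @param models a list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- c(min(m$exons[, 1L]), max(m$exons[, 2L]))
    f <- function(type, s, e, attrs)
      sprintf("%s\tspotmap\t%s\t%d\t%d\t.\t%s\t.\t%s",
              m$contig, type, s, e, m$strand, attrs)
    lines <- c(lines,
      f("gene", span[1L], span[2L],
        sprintf("ID=%s;gene_symbol=%s", m$gene_id, m$gene_symbol)),
      f("mRNA", span[1L], span[2L],
        sprintf("ID=%s;Parent=%s;gene_symbol=%s", m$transcript_id, m$gene_id,
                m$gene_symbol)))
    for (i in seq_len(nrow(m$exons)))
      lines <- c(lines, f("exon", m$exons[i, 1L], m$exons[i, 2L],
                          sprintf("ID=%s.exon%d;Parent=%s", m$transcript_id,
                                  i, m$transcript_id)))
    for (i in seq_len(nrow(m$cds)))
      lines <- c(lines, f("CDS", m$cds[i, 1L], m$cds[i, 2L],
                          sprintf("ID=%s.cds%d;Parent=%s", m$transcript_id,
                                  i, m$transcript_id)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Apply variants to a reference window, producing the alternate haplotype
#'
#' Builds the alternate-species sequence of a window by applying the
#' variants that overlap it, and returns a coordinate map from reference
#' to alternate positions. Deleted reference positions map to the
#' preceding retained base and are flagged.
#'
#' @param g a [genome()].
#' @param variants a `variant_table` (only rows on `contig` overlapping
#'   the window are used). Variants must not overlap one another.
#' @param contig contig name.
#' @param start,end 1-based inclusive window bounds.
#' @return a list with `alt_seq` (string), `map` (data.frame with
#'   `ref_pos`, `alt_pos`, `deleted` for every reference position in the
#'   window; `alt_pos` is window-local, 1-based), and `shift` (total
#'   length change).
#' @export
apply_variants <- function(g, variants, contig, start, end) {
  s <- contig_seq(g, contig)
  if (start < 1L || end > nchar(s) || start > end)
    stop("window out of range")
  v <- variants[variants$contig == contig, , drop = FALSE]
  v <- v[v$pos <= end & (v$pos + nchar(v$ref) - 1L) >= start, , drop = FALSE]
  v <- v[order(v$pos), , drop = FALSE]
  if (nrow(v) > 1L) {
    ends <- v$pos + nchar(v$ref) - 1L
    bad <- which(v$pos[-1L] <= ends[-nrow(v)])
    if (length(bad))
      stop("overlapping variants at ", contig, ":", v$pos[bad[1L]],
           " and ", contig, ":", v$pos[bad[1L] + 1L])
  }
  if (nrow(v) > 0L && (v$pos[1L] < start ||
                       max(v$pos + nchar(v$ref) - 1L) > end))
    stop("variant extends beyond window; widen the window")

  ref_pos <- start:end
  n <- length(ref_pos)
  alt_pos <- integer(n); deleted <- logical(n)
  out <- character(0L)
  cur_ref <- start; cur_alt <- 0L
  vi <- 1L
  while (cur_ref <= end) {
    if (vi <= nrow(v) && v$pos[vi] == cur_ref) {
      rlen <- nchar(v$ref[vi]); alen <- nchar(v$alt[vi])
      out <- c(out, v$alt[vi])
      shared <- min(rlen, alen)
      for (k in seq_len(rlen)) {
        idx <- cur_ref - start + k
        if (k <= shared) {
          alt_pos[idx] <- cur_alt + k; deleted[idx] <- FALSE
        } else {                      # deleted base: map to preceding kept
          alt_pos[idx] <- cur_alt + shared; deleted[idx] <- TRUE
        }
      }
      cur_alt <- cur_alt + alen
      cur_ref <- cur_ref + rlen
      vi <- vi + 1L
    } else {
      nxt <- if (vi <= nrow(v)) v$pos[vi] - 1L else end
      out <- c(out, substr(s, cur_ref, nxt))
      len <- nxt - cur_ref + 1L
      idx <- (cur_ref - start + 1L):(nxt - start + 1L)
      alt_pos[idx] <- cur_alt + seq_len(len)
      cur_alt <- cur_alt + len
      cur_ref <- nxt + 1L
    }
  }
  alt_seq <- paste0(out, collapse = "")
  list(alt_seq = alt_seq,
       map = data.frame(ref_pos = ref_pos, alt_pos = alt_pos,
                        deleted = deleted),
       shift = nchar(alt_seq) - n)
}
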