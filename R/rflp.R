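# Discovery of site-disrupting variants, diagnostic amplicon (CAPS/RFLP)
# marker design, and genotype calling from digest fragment patterns.

#' Compare recognition sites between a reference window and its
#' variant-applied counterpart
#'
#' A site is "lost in alt" when a reference site start has no matching
#' site at its mapped position in the alternate window; "gained in alt"
#' is the symmetric case. A variant may both destroy and create sites,
#' in which case both effects are returned.
#'
#' @param ref_window reference-window sequence.
#' @param alt_window alternate-window sequence (same window, variants
#'   applied).
#' @param enz an [enzyme()].
#' @param map optional coordinate map (as returned by [apply_variants()],
#'   with window-local `alt_pos`); identity is assumed when absent.
#' @return character vector drawn from
#'   `c("site_lost_in_alt", "site_gained_in_alt")`; length 0 when the
#'   site sets correspond.
#' @export
site_diff <- function(ref_window, alt_window, enz, map = NULL) {
  ref_sites <- scan_sites(ref_window, enz)
  alt_sites <- scan_sites(alt_window, enz)
  if (is.null(map)) {
    n <- nchar(ref_window)
    map <- data.frame(ref_pos = seq_len(n), alt_pos = seq_len(n),
                      deleted = FALSE)
  }
  to_alt <- function(p) {
    i <- match(p, map$ref_pos - map$ref_pos[1L] + 1L)
    ifelse(map$deleted[i], NA_integer_, map$alt_pos[i])
  }
  mapped <- to_alt(ref_sites)
  lost <- any(is.na(mapped) | !(mapped %in% alt_sites))
  gained <- any(!(alt_sites %in% mapped[!is.na(mapped)]))
  out <- character(0L)
  if (lost) out <- c(out, "site_lost_in_alt")
  if (gained) out <- c(out, "site_gained_in_alt")
  out
}

#' Find variants that create or destroy recognition sites
#'
#' For every variant and enzyme, the local windows of radius
#' `len(recognition) - 1` around the variant's reference span are
#' compared with [site_diff()]; that radius is the smallest that cannot
#' miss an affected site. A variant may yield candidates for several
#' enzymes, and both a loss and a gain for the same enzyme.
#'
#' @param g a [genome()].
#' @param variants a `variant_table` validated against `g`.
#' @param enzymes list of [enzyme()] objects.
#' @return a `data.frame` of class `rflp_candidates` with one row per
#'   (variant, enzyme, effect): columns `contig`, `pos`, `ref`, `alt`,
#'   `kind`, `enzyme`, `effect`, `site_position` (start of the affected
#'   reference-strand site; for gains, the position in alt coordinates
#'   mapped back to the nearest reference base).
#' @export
find_rflp_variants <- function(g, variants, enzymes) {
  if (inherits(enzymes, "enzyme")) enzymes <- list(enzymes)
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    ctg <- variants$contig[i]
    clen <- nchar(contig_seq(g, ctg))
    vs <- variants$pos[i]
    ve <- vs + nchar(variants$ref[i]) - 1L
    for (enz in enzymes) {
      r <- nchar(enz$recognition) - 1L
      ws <- max(1L, vs - r); we <- min(clen, ve + r)
      ref_win <- substr(contig_seq(g, ctg), ws, we)
      appl <- apply_variants(g, variants[i, , drop = FALSE], ctg, ws, we)
      effects <- site_diff(ref_win, appl$alt_seq, enz, appl$map)
      for (eff in effects) {
        # locate the affected site for reporting
        sp <- NA_integer_
        refs <- scan_sites(ref_win, enz)
        alts <- scan_sites(appl$alt_seq, enz)
        to_alt <- function(p) {
          j <- match(p, appl$map$ref_pos - ws + 1L)
          ifelse(appl$map$deleted[j], NA_integer_, appl$map$alt_pos[j])
        }
        if (eff == "site_lost_in_alt") {
          m <- to_alt(refs)
          lostp <- refs[is.na(m) | !(m %in% alts)]
          if (length(lostp)) sp <- ws + lostp[1L] - 1L
        } else {
          m <- to_alt(refs)
          gl <- alts[!(alts %in% m[!is.na(m)])]
          if (length(gl)) {
            back <- appl$map$ref_pos[match(gl[1L], appl$map$alt_pos)]
            sp <- if (is.na(back)) vs else back
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          contig = ctg, pos = vs, ref = variants$ref[i],
          alt = variants$alt[i], kind = variants$kind[i],
          enzyme = enz$name, effect = eff, site_position = sp,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(contig = character(0L), pos = integer(0L),
                         ref = character(0L), alt = character(0L),
                         kind = character(0L), enzyme = character(0L),
                         effect = character(0L),
                         site_position = integer(0L),
                         stringsAsFactors = FALSE)
  class(out) <- c("rflp_candidates", "data.frame")
  out
}

# multiset match: same size and, after sorting, every |obs - exp| <= tol
.pattern_matches <- function(observed, expected, tolerance) {
  if (length(observed) != length(expected)) return(FALSE)
  all(abs(sort(observed) - sort(expected)) <= tolerance)
}

#' Design a diagnostic RFLP amplicon marker for a candidate
#'
#' Chooses an amplicon window containing the diagnostic site such that
#' (i) the length is within `[min_len, max_len]`, (ii) the cut-bearing
#' allele has no second site for the same enzyme inside the amplicon,
#' and (iii) the three genotype digest patterns (BW/BW, BW/PO as the
#' multiset union of the homozygotes, PO/PO) are pairwise
#' distinguishable at the configured gel resolution.
#'
#' @param g a [genome()].
#' @param candidate one row of [find_rflp_variants()] output (or a list
#'   with the same fields).
#' @param variants the full `variant_table` (used to build the PO allele
#'   of the amplicon; only the candidate variant itself is applied).
#' @param min_len,max_len amplicon length bounds (defaults 200-600 bp,
#'   the range practical for agarose-gel genotyping).
#' @param gel_resolution minimum fragment-length difference resolvable
#'   on the gel (default 20 bp).
#' @return an object of class `rflp_marker` (fields `candidate`,
#'   `amplicon` = c(start, end), `enzyme`, `pattern_by_genotype`), or an
#'   object of class `rflp_design_failure` with a `reason` when no
#'   admissible window exists.
#' @export
design_marker <- function(g, candidate, variants = NULL,
                          min_len = 200L, max_len = 600L,
                          gel_resolution = 20L) {
  if (min_len >= max_len) stop("min_len must be < max_len")
  cand <- as.list(candidate)
  enz <- enzyme_catalog()[[cand$enzyme]]
  if (is.null(enz)) stop("enzyme not in catalog: ", cand$enzyme)
  clen <- nchar(contig_seq(g, cand$contig))
  if (is.null(variants))
    variants <- variant_table(cand$contig, cand$pos, cand$ref, cand$alt)
  vrow <- variants[variants$contig == cand$contig &
                   variants$pos == cand$pos, , drop = FALSE][1L, , drop = FALSE]
  site <- cand$site_position
  w <- nchar(enz$recognition)

  try_window <- function(ws, we) {
    if (ws < 1L || we > clen) return(NULL)
    span_lo <- min(site, vrow$pos)
    span_hi <- max(site + w - 1L, vrow$pos + nchar(vrow$ref) - 1L)
    if (ws > span_lo - 1L || we < span_hi + 1L) return(NULL)
    bw_seq <- substr(contig_seq(g, cand$contig), ws, we)
    po_seq <- apply_variants(g, vrow, cand$contig, ws, we)$alt_seq
    cut_allele <- if (cand$effect == "site_lost_in_alt") bw_seq else po_seq
    if (length(scan_sites(cut_allele, enz)) != 1L) return(NULL)
    p_bw <- digest_fragments(bw_seq, enz)$fragment_lengths
    p_po <- digest_fragments(po_seq, enz)$fragment_lengths
    p_het <- sort(c(p_bw, p_po))
    pats <- list(`BW/BW` = p_bw, `BW/PO` = p_het, `PO/PO` = p_po)
    for (a in 1:2) for (b in (a + 1):3)
      if (.pattern_matches(pats[[a]], pats[[b]], gel_resolution - 1L))
        return(NULL)
    structure(list(candidate = cand,
                   amplicon = c(start = ws, end = we),
                   enzyme = enz$name,
                   pattern_by_genotype = pats,
                   gel_resolution = gel_resolution),
              class = "rflp_marker")
  }

  # Feasible windows must fully contain no second site of the enzyme on
  # the cut-bearing allele: locate the neighbouring sites and derive the
  # admissible start range, then verify candidate windows exactly.
  region_lo <- max(1L, site - max_len - 30L)
  region_hi <- min(clen, site + w - 1L + max_len + 30L)
  if (cand$effect == "site_lost_in_alt") {
    sites_cut <- scan_sites(substr(contig_seq(g, cand$contig), region_lo,
                                   region_hi), enz) + region_lo - 1L
  } else {
    appl <- apply_variants(g, vrow, cand$contig, region_lo, region_hi)
    alt_sites <- scan_sites(appl$alt_seq, enz)
    sites_cut <- appl$map$ref_pos[match(alt_sites, appl$map$alt_pos)]
    sites_cut[is.na(sites_cut)] <- site   # starts on inserted bases
  }
  others <- setdiff(sites_cut, site)
  lnb <- suppressWarnings(max(others[others < site]))
  rnb <- suppressWarnings(min(others[others > site]))
  a_lo <- max(1L, if (is.finite(lnb)) lnb + 1L else 1L)
  b_hi <- min(clen, if (is.finite(rnb)) rnb + w - 2L else clen)
  span_lo <- min(site, vrow$pos)
  span_hi <- max(site + w - 1L, vrow$pos + nchar(vrow$ref) - 1L)
  for (len in seq(min_len, max_len, by = 1L)) {
    ws_lo <- max(a_lo, span_hi + 2L - len)
    ws_hi <- min(span_lo - 1L, b_hi - len + 1L)
    if (ws_lo > ws_hi) next
    centre_ws <- site + w %/% 2L - len %/% 2L
    cand_ws <- unique(pmin(pmax(c(centre_ws, (ws_lo + ws_hi) %/% 2L,
                                  ws_lo, ws_hi), ws_lo), ws_hi))
    for (ws in cand_ws) {
      m <- try_window(ws, ws + len - 1L)
      if (!is.null(m)) return(m)
    }
  }
  structure(list(candidate = cand,
                 reason = paste("no amplicon window of length",
                                min_len, "-", max_len,
                                "yields a single diagnostic cut with",
                                "gel-distinguishable genotype patterns")),
            class = "rflp_design_failure")
}

#' @exportS3Method base::print
print.rflp_marker <- function(x, ...) {
  cat(sprintf("rflp_marker %s @ %s:%d-%d (%d bp)\n", x$enzyme,
              x$candidate$contig, x$amplicon[["start"]],
              x$amplicon[["end"]],
              x$amplicon[["end"]] - x$amplicon[["start"]] + 1L))
  for (gt in names(x$pattern_by_genotype))
    cat(sprintf("  %-6s %s\n", gt,
                paste(x$pattern_by_genotype[[gt]], collapse = " + ")))
  invisible(x)
}

#' @exportS3Method base::print
print.rflp_design_failure <- function(x, ...) {
  cat("rflp design failure:", x$reason, "\n")
  invisible(x)
}

#' Call a genotype from observed digest fragments
#'
#' Multiset matching: the observed fragment lengths are compared with
#' each genotype's expected pattern; a call is made only when exactly
#' one genotype matches within the per-fragment tolerance, otherwise
#' `no_call` (the ambiguity rule that protects against partial gels).
#'
#' @param marker an `rflp_marker`.
#' @param observed_fragments numeric vector of observed fragment lengths.
#' @param tolerance per-fragment length tolerance in bp (default 10).
#' @return one of `"BW/BW"`, `"BW/PO"`, `"PO/PO"`, `"no_call"`.
#' @export
call_genotype <- function(marker, observed_fragments, tolerance = 10) {
  if (length(observed_fragments) == 0L) stop("no observed fragments")
  hits <- names(which(vapply(marker$pattern_by_genotype, .pattern_matches,
                             logical(1L), observed = observed_fragments,
                             tolerance = tolerance)))
  if (length(hits) == 1L) hits else "no_call"
}

#' Export candidates as TSV
#' @param candidates output of [find_rflp_variants()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  write.table(candidates, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
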