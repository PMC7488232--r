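# Backcross statistics: goodness-of-fit tests with integer-rounded
# expectations, exclusion/linkage testing, interval refinement,
# segregation distortion, modifier-locus count inference, and Welch's t
# from summary statistics.

# round half away from zero (R's round() is banker's rounding)
.round_half_up <- function(x) floor(x + 0.5)

#' Chi-square goodness-of-fit test with integer-rounded expectations
#'
#' Expected counts are formed as `round-half-up(N * f_i)` for every
#' class but the last, with the last class taken as the complement so
#' the expectations always sum to N exactly — the convention used when
#' expectations are quoted as whole animals (e.g. "63 expected" out of
#' 125 under 1:1). No continuity correction is applied. The unrounded
#' statistic is reported alongside.
#'
#' @param observed vector of non-negative integer counts.
#' @param expected_fractions vector of class probabilities summing to 1.
#' @param round_expected round expectations to whole counts (default
#'   TRUE).
#' @return object of class `gof_result`: `observed`, `expected`,
#'   `chi2`, `df` (= classes - 1), `p` (upper tail), plus
#'   `expected_raw` / `chi2_raw` / `p_raw` for the unrounded version.
#' @export
chi_square_gof <- function(observed, expected_fractions,
                           round_expected = TRUE) {
  if (length(observed) != length(expected_fractions))
    stop("observed and expected_fractions differ in length")
  if (any(observed < 0) || any(observed != floor(observed)))
    stop("observed must be non-negative integers")
  if (abs(sum(expected_fractions) - 1) > 1e-9)
    stop("expected fractions must sum to 1")
  N <- sum(observed)
  if (N == 0) stop("N = 0")
  k <- length(observed)
  e_raw <- N * expected_fractions
  if (any(e_raw == 0)) stop("expected count of zero")
  if (round_expected) {
    e <- .round_half_up(e_raw)
    e[k] <- N - sum(e[-k])
    # tiny N can round a class with positive raw expectation to zero;
    # fall back to the unrounded expectations there
    if (any(e == 0)) e <- e_raw
  } else e <- e_raw
  if (any(e == 0)) stop("expected count of zero")
  chi2 <- sum((observed - e)^2 / e)
  chi2_raw <- sum((observed - e_raw)^2 / e_raw)
  df <- k - 1L
  structure(list(observed = observed, expected = e, chi2 = chi2, df = df,
                 p = pchisq(chi2, df, lower.tail = FALSE),
                 expected_raw = e_raw, chi2_raw = chi2_raw,
                 p_raw = pchisq(chi2_raw, df, lower.tail = FALSE),
                 n = N),
            class = "gof_result")
}

#' @exportS3Method base::print
print.gof_result <- function(x, ...) {
  cat(sprintf("X^2(%d, N = %d) = %.2f, p = %.3g\n", x$df, x$n, x$chi2, x$p))
  cat("  observed:", paste(x$observed, collapse = ", "),
      "| expected:", paste(x$expected, collapse = ", "), "\n")
  invisible(x)
}

#' Exclusion / linkage test at one marker
#'
#' In a backcross of an F1 carrier to the PO stock, every affected
#' animal must carry the BW allele at a locus linked to the causal
#' mutation. A marker is excluded when at least `exclusion_threshold`
#' affected animals are homozygous PO there (default 2: a single
#' homozygote could be a genotyping artefact; set 1 for the strict
#' genetic rule). The accompanying goodness-of-fit compares the
#' heterozygote/homozygote split with the unlinked 1:1 expectation.
#'
#' @param calls character vector of genotype calls for affected N2
#'   animals at the marker, in `c("BW/PO", "PO/PO", "no_call")`;
#'   no-calls are dropped and counted.
#' @param marker_name label for reporting.
#' @param exclusion_threshold minimum PO/PO affected animals to exclude.
#' @return object of class `linkage_result`: `marker_name`,
#'   `n_affected`, `n_het`, `n_hom_po`, `n_no_call`, `verdict`
#'   (`"linked"` / `"excluded"`), `gof`.
#' @export
exclusion_test <- function(calls, marker_name = "marker",
                           exclusion_threshold = 2L) {
  bad <- setdiff(unique(calls), c("BW/PO", "PO/PO", "no_call"))
  if (length(bad)) stop("unexpected genotype call(s): ",
                        paste(bad, collapse = ", "))
  n_no_call <- sum(calls == "no_call")
  calls <- calls[calls != "no_call"]
  if (length(calls) == 0L) stop("no usable genotype calls")
  n_het <- sum(calls == "BW/PO")
  n_hom <- sum(calls == "PO/PO")
  structure(list(marker_name = marker_name,
                 n_affected = n_het + n_hom, n_het = n_het,
                 n_hom_po = n_hom, n_no_call = n_no_call,
                 verdict = if (n_hom >= exclusion_threshold) "excluded"
                           else "linked",
                 gof = chi_square_gof(c(n_het, n_hom), c(0.5, 0.5))),
            class = "linkage_result")
}

#' @exportS3Method base::print
print.linkage_result <- function(x, ...) {
  cat(sprintf("%s: %s (%d affected: %d BW/PO, %d PO/PO%s)\n",
              x$marker_name, x$verdict, x$n_affected, x$n_het, x$n_hom_po,
              if (x$n_no_call) paste0(", ", x$n_no_call, " no_call")
              else ""))
  print(x$gof)
  invisible(x)
}

#' Refine the linked interval from ordered markers
#'
#' The linked block is the run of markers at which every affected
#' animal is heterozygous; the interval is bounded by the nearest
#' flanking markers showing at least one PO/PO affected animal
#' (recombinants). A side with no recombinant marker is open-ended and
#' flagged.
#'
#' @param marker_names markers in map order.
#' @param genotypes character matrix (affected animals x markers) of
#'   `"BW/PO"` / `"PO/PO"` calls.
#' @return list with `left`, `right` (flanking marker names or `NA`
#'   when open), `block` (marker names het in all animals), `open_left`,
#'   `open_right`.
#' @export
linked_interval <- function(marker_names, genotypes) {
  stopifnot(ncol(genotypes) == length(marker_names))
  all_het <- apply(genotypes == "BW/PO", 2L, all)
  if (!any(all_het)) stop("no linked block: no marker is heterozygous in all affected animals")
  block <- which(all_het)
  lo <- min(block); hi <- max(block)
  left_cands <- which(!all_het & seq_along(marker_names) < lo)
  right_cands <- which(!all_het & seq_along(marker_names) > hi)
  list(left = if (length(left_cands)) marker_names[max(left_cands)]
       else NA_character_,
       right = if (length(right_cands)) marker_names[min(right_cands)]
       else NA_character_,
       block = marker_names[block],
       open_left = length(left_cands) == 0L,
       open_right = length(right_cands) == 0L)
}

#' Segregation-distortion test for a dominant trait in a backcross
#'
#' Tests the observed affected/unaffected split against the Mendelian
#' 1:1 expectation, with whole-animal expected counts (see
#' [chi_square_gof()]).
#'
#' @param n_affected,n_total counts.
#' @return a `gof_result`.
#' @export
segregation_test <- function(n_affected, n_total) {
  if (n_total == 0) stop("n_total = 0")
  if (n_affected < 0 || n_affected > n_total)
    stop("n_affected must be in [0, n_total]")
  chi_square_gof(c(n_affected, n_total - n_affected), c(0.5, 0.5))
}

#' Expected fraction of backcross offspring resembling the F1 parent
#'
#' With k unlinked biallelic modifier loci, a backcross offspring
#' reproduces the F1 parent's modifier configuration (heterozygous at
#' every locus) with probability 2^-k: 50% for one locus, 25% for two,
#' 12.5% for three.
#'
#' @param k number of modifier loci (integer >= 1).
#' @return 2^-k.
#' @export
expected_resemblance_fraction <- function(k) {
  if (length(k) != 1L || k < 1 || k != floor(k))
    stop("k must be an integer >= 1")
  2^(-k)
}

#' Infer the number of modifier loci from resemblance counts
#'
#' For each candidate modifier count k, the observed
#' resemble / not-resemble split is tested against the expected
#' `2^-k : 1 - 2^-k` ratio; values of k not rejected at `alpha` are
#' retained.
#'
#' @param n_resemble number of affected offspring resembling the F1
#'   parent.
#' @param n_total number of affected offspring scored.
#' @param k_range candidate modifier counts (default 1:3).
#' @param alpha rejection level (default 0.05).
#' @param round_expected passed to [chi_square_gof()].
#' @return object of class `modifier_inference`: `n_resemble`,
#'   `n_total`, `per_k` (named list of `gof_result`), `alpha`,
#'   `retained_k`.
#' @export
modifier_inference <- function(n_resemble, n_total, k_range = 1:3,
                               alpha = 0.05, round_expected = TRUE) {
  if (n_resemble < 0 || n_resemble > n_total)
    stop("n_resemble must be in [0, n_total]")
  if (length(k_range) == 0L) stop("empty k_range")
  per_k <- lapply(k_range, function(k) {
    f <- expected_resemblance_fraction(k)
    chi_square_gof(c(n_resemble, n_total - n_resemble), c(f, 1 - f),
                   round_expected = round_expected)
  })
  names(per_k) <- as.character(k_range)
  p <- vapply(per_k, `[[`, numeric(1L), "p")
  structure(list(n_resemble = n_resemble, n_total = n_total,
                 per_k = per_k, alpha = alpha,
                 retained_k = k_range[p >= alpha]),
            class = "modifier_inference")
}

#' @exportS3Method base::print
print.modifier_inference <- function(x, ...) {
  cat(sprintf("modifier_inference: %d of %d resemble the F1 parent\n",
              x$n_resemble, x$n_total))
  for (k in names(x$per_k)) {
    g <- x$per_k[[k]]
    cat(sprintf("  k = %s (expect %.1f%%): X^2(%d, N = %d) = %.2f, p = %.3g%s\n",
                k, 100 * expected_resemblance_fraction(as.integer(k)),
                g$df, g$n, g$chi2, g$p,
                if (g$p < x$alpha) "  [rejected]" else ""))
  }
  cat("  retained k:", paste(x$retained_k, collapse = ", "), "\n")
  invisible(x)
}

#' Welch's two-sample t-test from summary statistics
#'
#' Unequal-variance comparison of two group means given only
#' `(mean, sd, n)` summaries. Degrees of freedom follow
#' Welch-Satterthwaite; the reported integer df is the floor of the
#' real value, while the p-value is computed at the unfloored df.
#'
#' @param m1,s1,n1 mean, sd, and size of group 1.
#' @param m2,s2,n2 mean, sd, and size of group 2.
#' @return object of class `welch_result`: `t`, `df_raw`, `df_report`,
#'   `p` (two-sided), and the group summaries.
#' @export
welch_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (s1 <= 0 || s2 <= 0) stop("group sds must be > 0")
  se2 <- s1^2 / n1 + s2^2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df_raw <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  structure(list(t = t, df_raw = df_raw, df_report = floor(df_raw),
                 p = 2 * pt(-abs(t), df_raw),
                 group1 = c(mean = m1, sd = s1, n = n1),
                 group2 = c(mean = m2, sd = s2, n = n2)),
            class = "welch_result")
}

#' @exportS3Method base::print
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch's t(%d) = %.2f, p = %.3g  (df_raw = %.2f)\n",
              x$df_report, x$t, x$p, x$df_raw))
  invisible(x)
}
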