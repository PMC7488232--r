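# Synthetic-data generators: genome pairs with planted site-disrupting
# variants and gene models, and simulated backcross / intercross
# pedigrees. Every generator is a pure function of (config, seed) and
# records its ground truth, so downstream stages can be scored exactly.

#' Configuration for the synthetic genome pair
#'
#' Defaults emulate the interspecific divergence the pipeline was built
#' for: one variant per 68 bp, of which 89.3% SNPs and 5.35% each short
#' insertions and deletions (proportions taken from the genome-wide
#' variant class counts of the motivating cross).
#'
#' @param n_contigs,contig_length genome shape.
#' @param variant_rate_bp mean bases per variant (default 68).
#' @param snp_fraction,ins_fraction,del_fraction variant class mix; must
#'   sum to 1.
#' @param n_planted_rflp number of variants constructed to destroy a
#'   recognition site of a panel enzyme.
#' @param enzymes panel used for planting (default: six-base marker
#'   enzymes StuI, BamHI, KpnI, EcoRI, DraI, SphI; six-cutters leave
#'   enough site-free flank for amplicon design, as in practical CAPS
#'   work).
#' @param n_genes number of non-overlapping gene models to place.
#' @param seed RNG seed.
#' @return a list of class `genome_sim_config`.
#' @export
genome_sim_config <- function(n_contigs = 2L, contig_length = 50000L,
                              variant_rate_bp = 68,
                              snp_fraction = 0.893,
                              ins_fraction = 0.0535,
                              del_fraction = 0.0535,
                              n_planted_rflp = 10L,
                              enzymes = enzyme_catalog(
                                c("StuI", "BamHI", "KpnI", "EcoRI",
                                  "DraI", "SphI")),
                              n_genes = 6L, seed = 1L) {
  fr <- snp_fraction + ins_fraction + del_fraction
  if (abs(fr - 1) > 1e-9) stop("variant class fractions must sum to 1")
  if (variant_rate_bp <= 0) stop("variant_rate_bp must be positive")
  if (n_planted_rflp * 40L > n_contigs * contig_length / 10L)
    stop("infeasible planting density")
  structure(list(n_contigs = n_contigs, contig_length = contig_length,
                 variant_rate_bp = variant_rate_bp,
                 snp_fraction = snp_fraction, ins_fraction = ins_fraction,
                 del_fraction = del_fraction,
                 n_planted_rflp = n_planted_rflp, enzymes = enzymes,
                 n_genes = n_genes, seed = seed),
            class = "genome_sim_config")
}

.random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

.other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

#' Generate a synthetic genome pair with known ground truth
#'
#' Builds a reference genome of i.i.d. bases, places neutral variants at
#' the configured rate and class mix, plants `n_planted_rflp` SNPs each
#' of which destroys one recognition site of a panel enzyme (the site is
#' first written into the reference, then broken in the alternate
#' allele), and places non-overlapping gene models.
#'
#' @param config a [genome_sim_config()].
#' @return list with `genome`, `variants` (a `variant_table`),
#'   `gene_models`, and `truth` — a list holding `planted_rflp`
#'   (data.frame: contig, pos, enzyme, site_position), `variant_kinds`,
#'   and the gene placement table.
#' @export
simulate_genome_pair <- function(config) {
  set.seed(config$seed)
  cfg <- config
  contigs <- setNames(
    vapply(seq_len(cfg$n_contigs), function(i) .random_seq(cfg$contig_length),
           character(1L)),
    sprintf("ctg%02d", seq_len(cfg$n_contigs)))

  # --- plant enzyme sites, then break each with a SNP -------------------
  planted <- NULL
  occupied <- lapply(contigs, function(x) integer(0L))  # reserved positions
  if (cfg$n_planted_rflp > 0L) {
    per <- sample(names(contigs), cfg$n_planted_rflp, replace = TRUE)
    rows <- list()
    for (j in seq_len(cfg$n_planted_rflp)) {
      ctg <- per[j]
      enz <- cfg$enzymes[[sample(length(cfg$enzymes), 1L)]]
      w <- nchar(enz$recognition)
      repeat {
        sp <- sample(50L:(cfg$contig_length - 50L), 1L)
        if (!any(abs(sp - occupied[[ctg]]) < 60L)) break
      }
      occupied[[ctg]] <- c(occupied[[ctg]], sp)
      # write the site into the reference (concrete IUPAC instantiation)
      site_seq <- vapply(strsplit(enz$recognition, "")[[1]], function(code) {
        opts <- strsplit(c(A = "A", C = "C", G = "G", T = "T", R = "AG",
                           Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                           B = "CGT", D = "AGT", H = "ACT", V = "ACG",
                           N = "ACGT")[[code]], "")[[1]]
        sample(opts, 1L)
      }, character(1L))
      site_seq <- paste(site_seq, collapse = "")
      s <- contigs[[ctg]]
      substr(s, sp, sp + w - 1L) <- site_seq
      # pick a SNP inside the site that destroys it (re-scan to verify)
      repeat {
        k <- sample(w, 1L)
        b <- substr(site_seq, k, k)
        nb <- .other_base(b)
        alt_site <- site_seq; substr(alt_site, k, k) <- nb
        win <- paste0(substr(s, max(1L, sp - w), sp - 1L), alt_site,
                      substr(s, sp + w, min(nchar(s), sp + 2L * w - 1L)))
        if (length(scan_sites(alt_site, enz)) == 0L &&
            length(scan_sites(win, enz)) == 0L) break
      }
      contigs[[ctg]] <- s
      rows[[j]] <- data.frame(contig = ctg, pos = sp + k - 1L,
                              ref = b, alt = nb, enzyme = enz$name,
                              site_position = sp, stringsAsFactors = FALSE)
    }
    planted <- do.call(rbind, rows)
  }

  # --- neutral variants -------------------------------------------------
  vt_rows <- list()
  for (ctg in names(contigs)) {
    s <- contigs[[ctg]]
    n <- nchar(s)
    # Bernoulli placement keeps the count Binomial(L, 1/rate). Adjacent
    # SNPs/insertions never overlap (anchored edits); only deletions
    # need clearance, so a deletion's length is capped by the gap to the
    # next variant (demoted to a SNP when there is no room).
    pos <- which(runif(n) < 1 / cfg$variant_rate_bp)
    res <- occupied[[ctg]]
    if (length(res))
      pos <- pos[vapply(pos, function(p) all(abs(p - res) >= 30L),
                        logical(1L))]
    pos <- pos[pos > 10L & pos < n - 10L]
    if (!length(pos)) next
    kinds <- sample(c("SNP", "insertion", "deletion"), length(pos),
                    replace = TRUE,
                    prob = c(cfg$snp_fraction, cfg$ins_fraction,
                             cfg$del_fraction))
    gap_next <- c(diff(pos), Inf)
    for (idx in seq_along(pos)) {
      p <- pos[idx]
      b <- substr(s, p, p)
      kind <- kinds[idx]
      dl_max <- min(8L, gap_next[idx] - 1L)
      if (kind == "deletion" && dl_max < 1L) kind <- "SNP"
      if (kind == "SNP") {
        vt_rows[[length(vt_rows) + 1L]] <- data.frame(
          contig = ctg, pos = p, ref = b, alt = .other_base(b),
          stringsAsFactors = FALSE)
      } else if (kind == "insertion") {
        ins <- .random_seq(sample(1:8, 1L))
        vt_rows[[length(vt_rows) + 1L]] <- data.frame(
          contig = ctg, pos = p, ref = b, alt = paste0(b, ins),
          stringsAsFactors = FALSE)
      } else {
        dl <- sample(seq_len(dl_max), 1L)
        vt_rows[[length(vt_rows) + 1L]] <- data.frame(
          contig = ctg, pos = p, ref = substr(s, p, p + dl),
          alt = b, stringsAsFactors = FALSE)
      }
    }
  }
  neutral <- if (length(vt_rows)) do.call(rbind, vt_rows) else NULL
  allv <- rbind(neutral,
                if (!is.null(planted))
                  planted[, c("contig", "pos", "ref", "alt")])
  allv <- allv[order(allv$contig, allv$pos), , drop = FALSE]
  g <- genome(contigs)
  variants <- variant_table(allv$contig, allv$pos, allv$ref, allv$alt, g)

  # --- gene models ------------------------------------------------------
  models <- list()
  if (cfg$n_genes > 0L) {
    slots_per <- ceiling(cfg$n_genes / cfg$n_contigs)
    gi <- 0L
    for (ctg in names(contigs)) {
      slot_w <- cfg$contig_length %/% (slots_per + 1L)
      for (sl in seq_len(slots_per)) {
        if (gi >= cfg$n_genes) break
        gi <- gi + 1L
        base <- (sl - 1L) * slot_w + 200L
        n_ex <- sample(1:3, 1L)
        ex <- matrix(0L, n_ex, 2L)
        cur <- base
        for (e in seq_len(n_ex)) {
          elen <- 3L * sample(20:60, 1L)
          ex[e, ] <- c(cur, cur + elen - 1L)
          cur <- cur + elen + sample(80:200, 1L)
        }
        models[[gi]] <- gene_model(
          gene_id = sprintf("gene%03d", gi),
          transcript_id = sprintf("tx%03d", gi),
          contig = ctg, strand = sample(c("+", "-"), 1L),
          exons = ex, cds = ex,
          gene_symbol = sprintf("Gene%03d", gi))
      }
    }
  }

  list(genome = g, variants = variants, gene_models = models,
       truth = list(planted_rflp = planted,
                    variant_kinds = variants$kind,
                    n_neutral = if (is.null(neutral)) 0L else nrow(neutral)))
}

#' Configuration for the simulated backcross
#'
#' Defaults are the study conditions of the motivating cross: 6 F1
#' carriers, 125 N2 offspring, a dominant causal locus carried on the
#' BW haplotype with homozygous lethality, two unlinked modifier loci
#' whose PO alleles shrink the spot and (when homozygous at every
#' modifier) rescue the phenotype, and spot-size calibration targets of
#' 77.6 +/- 36.6 mm^2 on the pure BW background and 3.75 +/- 1.56 mm^2
#' for the F1 configuration.
#'
#' @param n_f1,n_n2 pedigree sizes.
#' @param marker_positions_cM genetic-map positions (cM) of the typed
#'   markers on the causal chromosome.
#' @param causal_marker_index index of the marker cosegregating with
#'   the causal locus.
#' @param k_modifiers number of unlinked modifier loci.
#' @param rescue_prob probability that a carrier homozygous PO at every
#'   modifier locus shows no spot.
#' @param spot_bw,spot_f1 `(mean, sd)` spot-size calibration targets in
#'   mm^2 for the 0-PO-allele and k-PO-allele modifier backgrounds.
#' @param f1_band central probability mass of the F1 size distribution
#'   used to define "resembles the F1 parent" (default 0.95).
#' @param s_homozygote_lethal flag used by [simulate_intercross()].
#' @param seed RNG seed.
#' @return a list of class `cross_sim_config`.
#' @export
cross_sim_config <- function(n_f1 = 6L, n_n2 = 125L,
                             marker_positions_cM = seq(0, 45, by = 5),
                             causal_marker_index = 5L,
                             k_modifiers = 2L,
                             rescue_prob = 1.0,
                             spot_bw = c(77.6, 36.6),
                             spot_f1 = c(3.75, 1.56),
                             f1_band = 0.95,
                             s_homozygote_lethal = TRUE,
                             seed = 1L) {
  if (rescue_prob < 0 || rescue_prob > 1) stop("rescue_prob must be in [0,1]")
  if (k_modifiers < 0L) stop("k_modifiers must be >= 0")
  if (spot_bw[2L] <= 0 || spot_f1[2L] <= 0) stop("spot-size sds must be > 0")
  if (causal_marker_index < 1L ||
      causal_marker_index > length(marker_positions_cM))
    stop("causal_marker_index out of range")
  structure(list(n_f1 = n_f1, n_n2 = n_n2,
                 marker_positions_cM = marker_positions_cM,
                 causal_marker_index = causal_marker_index,
                 k_modifiers = k_modifiers, rescue_prob = rescue_prob,
                 spot_bw = spot_bw, spot_f1 = spot_f1, f1_band = f1_band,
                 s_homozygote_lethal = s_homozygote_lethal, seed = seed),
            class = "cross_sim_config")
}

# lognormal parameters from an arithmetic (mean, sd)
.lnorm_par <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

# location/scale for a given count of PO modifier alleles: linear in the
# allele count between the BW (0 alleles) and F1 (k alleles) anchors.
.spot_par <- function(cfg, n_po_alleles) {
  k <- max(cfg$k_modifiers, 1L)
  bw <- .lnorm_par(cfg$spot_bw[1L], cfg$spot_bw[2L])
  f1 <- .lnorm_par(cfg$spot_f1[1L], cfg$spot_f1[2L])
  a <- n_po_alleles / k
  mu <- bw[["mu"]] + a * (f1[["mu"]] - bw[["mu"]])
  sigma <- max(0.05, bw[["sigma"]] + a * (f1[["sigma"]] - bw[["sigma"]]))
  c(mu = mu, sigma = sigma)
}

#' Simulate the interspecific backcross
#'
#' F1 carriers are heterozygous BW/PO at every locus and carry the
#' dominant causal allele on the BW haplotype. N2 offspring receive a
#' PO gamete from the PO parent and a recombinant F1 gamete: linked
#' markers recombine under the Haldane map function (no interference);
#' modifier loci are unlinked. A carrier is spotted unless rescued
#' (rescue acts only on carriers homozygous PO at every modifier
#' locus, with probability `rescue_prob`). Spotted animals draw a spot
#' size from a lognormal whose log-scale location decreases with each
#' PO modifier allele, anchored at the BW and F1 calibration targets;
#' `resembles_f1` marks sizes inside the central `f1_band` of the F1
#' size distribution.
#'
#' @param config a [cross_sim_config()].
#' @return object of class `pedigree`: a list with `animals` (data.frame:
#'   id, generation, carrier, spotted, spot_size_mm2, resembles_f1,
#'   n_po_modifier_alleles), `marker_genotypes` (N2 x markers character
#'   matrix of "BW/PO"/"PO/PO"), `modifier_genotypes` (N2 x k matrix),
#'   and the config.
#' @export
simulate_backcross <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  nm <- length(cfg$marker_positions_cM)
  n <- cfg$n_n2
  # F1 gamete: allele per marker, Haldane recombination between adjacents
  d <- diff(cfg$marker_positions_cM)
  rfrac <- 0.5 * (1 - exp(-2 * d / 100))
  first <- sample(c("BW", "PO"), n, replace = TRUE)
  gam <- matrix("", n, nm)
  gam[, 1L] <- first
  if (nm > 1L) for (j in 2:nm) {
    rec <- runif(n) < rfrac[j - 1L]
    gam[, j] <- ifelse(rec, ifelse(gam[, j - 1L] == "BW", "PO", "BW"),
                       gam[, j - 1L])
  }
  marker_geno <- matrix(ifelse(gam == "BW", "BW/PO", "PO/PO"), n, nm,
                        dimnames = list(NULL,
                          sprintf("m%02d", seq_len(nm))))
  carrier <- gam[, cfg$causal_marker_index] == "BW"
  k <- cfg$k_modifiers
  mod_geno <- if (k > 0L)
    matrix(sample(c("BW/PO", "PO/PO"), n * k, replace = TRUE), n, k,
           dimnames = list(NULL, sprintf("mod%d", seq_len(k))))
  else matrix(character(0L), n, 0L)
  n_po <- if (k > 0L)
    rowSums(mod_geno == "PO/PO") * 2L + rowSums(mod_geno == "BW/PO")
  else rep(0L, n)
  all_hom_po <- if (k > 0L) rowSums(mod_geno == "PO/PO") == k else FALSE
  rescued <- carrier & all_hom_po & (runif(n) < cfg$rescue_prob)
  spotted <- carrier & !rescued

  f1p <- .lnorm_par(cfg$spot_f1[1L], cfg$spot_f1[2L])
  zc <- -stats::qnorm((1 - cfg$f1_band) / 2)
  band <- exp(f1p[["mu"]] + c(-1, 1) * zc * f1p[["sigma"]])
  spot <- rep(NA_real_, n); resembles <- rep(NA, n)
  for (i in which(spotted)) {
    pp <- .spot_par(cfg, n_po[i])
    spot[i] <- exp(rnorm(1L, pp[["mu"]], pp[["sigma"]]))
    resembles[i] <- spot[i] >= band[1L] && spot[i] <= band[2L]
  }

  animals <- data.frame(
    id = c(sprintf("F1_%02d", seq_len(cfg$n_f1)),
           sprintf("N2_%03d", seq_len(n))),
    generation = c(rep("F1", cfg$n_f1), rep("N2", n)),
    carrier = c(rep(TRUE, cfg$n_f1), carrier),
    spotted = c(rep(TRUE, cfg$n_f1), spotted),
    spot_size_mm2 = c(exp(rnorm(cfg$n_f1, f1p[["mu"]], f1p[["sigma"]])),
                      spot),
    resembles_f1 = c(rep(TRUE, cfg$n_f1), resembles),
    stringsAsFactors = FALSE)
  animals$n_po_modifier_alleles <- c(rep(k, cfg$n_f1), n_po)
  structure(list(animals = animals, marker_genotypes = marker_geno,
                 modifier_genotypes = mod_geno, config = cfg),
            class = "pedigree")
}

#' @exportS3Method base::print
print.pedigree <- function(x, ...) {
  n2 <- x$animals[x$animals$generation == "N2", ]
  cat(sprintf("pedigree: %d F1, %d N2 (%d spotted, %d carriers)\n",
              sum(x$animals$generation == "F1"), nrow(n2),
              sum(n2$spotted), sum(n2$carrier)))
  invisible(x)
}

#' Simulate a carrier-by-carrier intercross
#'
#' Both parents are heterozygous carriers; offspring genotypes follow
#' the 1:2:1 Mendelian ratio. Homozygous-carrier embryos are flagged
#' lethal (resorbed) when `s_homozygote_lethal` is set, the regime
#' consistent with roughly a quarter of mid-gestation embryos showing
#' the lethal phenotype.
#'
#' @param config a [cross_sim_config()].
#' @param n_offspring number of conceptuses.
#' @return data.frame with `id`, `genotype` (`S/S`, `S/+`, `+/+`),
#'   `lethal`.
#' @export
simulate_intercross <- function(config, n_offspring = 100L) {
  set.seed(config$seed)
  a1 <- sample(c("S", "+"), n_offspring, replace = TRUE)
  a2 <- sample(c("S", "+"), n_offspring, replace = TRUE)
  geno <- ifelse(a1 == "S" & a2 == "S", "S/S",
          ifelse(a1 == "+" & a2 == "+", "+/+", "S/+"))
  data.frame(id = sprintf("E%03d", seq_len(n_offspring)),
             genotype = geno,
             lethal = geno == "S/S" & isTRUE(config$s_homozygote_lethal),
             stringsAsFactors = FALSE)
}

#' Write a pedigree's phenotype and genotype tables as TSV
#' @param ped a `pedigree`.
#' @param dir output directory (created if needed).
#' @return character vector of the two file paths, invisibly.
#' @export
write_pedigree_tsv <- function(ped, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "phenotypes.tsv")
  write.table(ped$animals, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  n2 <- ped$animals$generation == "N2"
  gt <- data.frame(animal_id = ped$animals$id[n2],
                   ped$marker_genotypes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  p2 <- file.path(dir, "genotypes.tsv")
  write.table(gt, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
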