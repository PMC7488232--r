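# Region classification and coding-consequence annotation.

test_that("region classification covers exon, UTR, splice, flank, intergenic", {
  sg <- simple_gene()
  g <- sg$genome; m <- sg$model; s <- sg$seq
  snp <- function(p) {
    b <- substr(s, p, p)
    variant_table("c1", p, b, setdiff(c("A", "C", "G", "T"), b)[1], g)
  }
  expect_equal(classify_region(snp(105), list(m))$category, "exon")
  # intron starts at 116: base 1-2 donor, base 3 splice_region, mid intron
  expect_setequal(classify_region(snp(117), list(m))$category,
                  c("intron", "splice_donor"))
  expect_setequal(classify_region(snp(118), list(m))$category,
                  c("intron", "splice_region"))
  expect_equal(classify_region(snp(140), list(m))$category, "intron")
  # intron ends at 169: acceptor on the last two bases
  expect_setequal(classify_region(snp(169), list(m))$category,
                  c("intron", "splice_acceptor"))
  # exonic bases 1-3 from the internal boundary are splice_region
  expect_setequal(classify_region(snp(114), list(m))$category,
                  c("exon", "splice_region"))
  # strand-aware flanks
  expect_equal(classify_region(snp(50), list(m))$category, "upstream5kb")
  expect_equal(classify_region(snp(250), list(m))$category, "downstream5kb")
  expect_equal(classify_region(snp(50), list())$category, "intergenic")
})

test_that("UTR categories follow CDS position and strand", {
  set.seed(401)
  s <- random_dna(800)
  substr(s, 161, 163) <- "ATG"
  substr(s, 218, 220) <- "TAA"   # CDS 161..220 (60 bases, complete)
  g <- genome(c(c1 = s))
  m <- gene_model("g1", "t1", "c1", "+", exons = rbind(c(101, 300)),
                  cds = rbind(c(161, 220)))
  snp <- function(p, gm) {
    b <- substr(s, p, p)
    classify_region(variant_table("c1", p, b,
                                  setdiff(c("A", "C", "G", "T"), b)[1], g),
                    list(gm))$category
  }
  expect_setequal(snp(120, m), c("exon", "utr5"))
  expect_setequal(snp(260, m), c("exon", "utr3"))
  m_neg <- gene_model("g1", "t1", "c1", "-", exons = rbind(c(101, 300)),
                      cds = rbind(c(161, 220)))
  expect_setequal(snp(120, m_neg), c("exon", "utr3"))
  expect_setequal(snp(260, m_neg), c("exon", "utr5"))
})

test_that("every variant receives at least one annotation (exhaustiveness)", {
  sg <- simple_gene()
  g <- sg$genome; s <- sg$seq
  set.seed(402)
  for (p in sample(seq_len(nchar(s)), 40)) {
    b <- substr(s, p, p)
    v <- variant_table("c1", p, b, setdiff(c("A", "C", "G", "T"), b)[1], g)
    ann <- classify_region(v, list(sg$model))
    expect_gte(nrow(ann), 1L)
    expect_true(all(ann$category %in% c(
      "exon", "intron", "utr5", "utr3", "splice_acceptor", "splice_donor",
      "splice_region", "upstream5kb", "downstream5kb", "intergenic")))
  }
})

test_that("coding consequences classify point changes and indels", {
  sg <- simple_gene()
  g <- sg$genome; m <- sg$model
  # CDS: ATG TCT CGA CTT GGG | TAC TAA
  ce <- coding_effect(variant_table("c1", 104, "T", "G", g), m, g)
  expect_equal(ce$effect, "missense")           # TCT -> GCT, Ser -> Ala
  expect_equal(c(ce$ref_aa, ce$alt_aa), c("S", "A"))
  expect_equal(ce$aa_position, 2L)
  ce2 <- coding_effect(variant_table("c1", 107, "C", "T", g), m, g)
  expect_equal(ce2$effect, "nonsense")          # CGA -> TGA
  ce3 <- coding_effect(variant_table("c1", 112, "T", "C", g), m, g)
  expect_equal(ce3$effect, "silent")            # CTT -> CTC
  # 3-base deletion aligned to a codon boundary
  ce4 <- coding_effect(variant_table("c1", 106, "TCGA", "T", g), m, g)
  expect_equal(ce4$effect, "inframe_deletion")
  ce5 <- coding_effect(variant_table("c1", 106, "T", "TA", g), m, g)
  expect_equal(ce5$effect, "frameshift")
  ce6 <- coding_effect(variant_table("c1", 106, "T", "TAAA", g), m, g)
  expect_equal(ce6$effect, "inframe_insertion")
  # start and stop disruption
  ce7 <- coding_effect(variant_table("c1", 101, "A", "C", g), m, g)
  expect_equal(ce7$effect, "start_lost")
  ce8 <- coding_effect(variant_table("c1", 173, "T", "C", g), m, g)
  expect_equal(ce8$effect, "stop_lost")         # TAA -> CAA
  # variant outside the CDS: no coding effect
  expect_null(coding_effect(variant_table("c1", 50, substr(sg$seq, 50, 50),
                                          if (substr(sg$seq, 50, 50) == "A")
                                            "C" else "A", g), m, g))
})

test_that("minus-strand classification mirrors the plus-strand case", {
  sg <- simple_gene()
  s <- sg$seq; L <- nchar(s)
  g2 <- genome(c(c1 = rc(s)))
  m2 <- gene_model("geneA", "txA", "c1", "-",
                   exons = rbind(L + 1 - c(175, 170), L + 1 - c(115, 101)),
                   cds   = rbind(L + 1 - c(175, 170), L + 1 - c(115, 101)))
  mirror <- function(p, ref, alt)
    variant_table("c1", L + 1 - p, rc(ref), rc(alt), g2)
  ce <- coding_effect(mirror(104, "T", "G"), m2, g2)
  expect_equal(ce$effect, "missense")
  expect_equal(c(ce$ref_aa, ce$alt_aa, ce$aa_position), c("S", "A", "2"))
  ce2 <- coding_effect(mirror(107, "C", "T"), m2, g2)
  expect_equal(ce2$effect, "nonsense")
  ce3 <- coding_effect(mirror(112, "T", "C"), m2, g2)
  expect_equal(ce3$effect, "silent")
})

test_that("SNP consequences agree with an independent translate-and-compare oracle", {
  skip_if_not_installed("seqinr")
  set.seed(403)
  for (rep in 1:6) {
    # random complete CDS as a single-exon gene
    n_codon <- sample(20:60, 1)
    body <- paste(sample(setdiff(
      apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                        c("A","C","G","T")), 1, paste, collapse = ""),
      c("TAA", "TAG", "TGA")), n_codon - 2, replace = TRUE), collapse = "")
    cds <- paste0("ATG", body, "TAA")
    flank <- random_dna(40)
    g <- genome(c(c1 = paste0(flank, cds, random_dna(40))))
    m <- gene_model("g", "t", "c1", "+",
                    exons = rbind(c(41, 40 + nchar(cds))),
                    cds = rbind(c(41, 40 + nchar(cds))))
    for (k in 1:15) {
      p <- sample(seq(41, 40 + nchar(cds)), 1)
      b <- substr(contig_seq(g, "c1"), p, p)
      v <- variant_table("c1", p, b, sample(setdiff(c("A","C","G","T"), b), 1), g)
      ce <- coding_effect(v, m, g)
      cds_alt <- cds
      substr(cds_alt, p - 40, p - 40) <- v$alt
      diffs <- oracle_aa_diff(cds, cds_alt)
      aa_alt <- seqinr::translate(strsplit(tolower(cds_alt), "")[[1]])
      if (length(diffs) == 0) {
        expect_equal(ce$effect, "silent")
      } else if (aa_alt[diffs[1]] == "*") {
        expect_equal(ce$effect, "nonsense")
      } else if (diffs[1] == 1 && substr(cds, 1, 3) == "ATG") {
        expect_equal(ce$effect, "start_lost")
      } else if (diffs[1] == n_codon && aa_alt[diffs[1]] != "*") {
        expect_equal(ce$effect, "stop_lost")
      } else {
        expect_equal(ce$effect, "missense")
      }
      expect_equal(ce$aa_position, (p - 40 + 2) %/% 3)
    }
  }
})

test_that("summaries count with multiplicity and compute the variant rate", {
  sg <- simple_gene()
  g <- sg$genome; m <- sg$model; s <- sg$seq
  v <- variant_table(rep("c1", 4), c(104L, 112L, 140L, 50L),
                     c("T", "T", substr(s, 140, 140), substr(s, 50, 50)),
                     c("G", "C",
                       setdiff(c("A","C","G","T"), substr(s, 140, 140))[1],
                       setdiff(c("A","C","G","T"), substr(s, 50, 50))[1]), g)
  sm <- summarize_effects(v, list(m), g, covered_length = 272)
  expect_equal(sm$variant_rate_bp, 68)
  expect_equal(unname(sm$region_counts["exon"]), 2L)
  expect_equal(unname(sm$region_counts["intron"]), 1L)
  expect_equal(unname(sm$region_counts["upstream5kb"]), 1L)
  expect_equal(unname(sm$effect_counts["missense"]), 1L)
  expect_equal(unname(sm$effect_counts["silent"]), 1L)
  expect_equal(sm$n_genes_with_cds_snp, 1L)
  expect_equal(sm$n_genes_nonsynonymous, 1L)
  expect_error(summarize_effects(v, list(m), g, covered_length = 0),
               "positive")
  # rate identity at scale: N variants over 68 N covered bases -> 68
  expect_equal(summarize_effects(v, list(), g,
                                 covered_length = 68 * nrow(v))$variant_rate_bp,
               68)
})

test_that("gene rollups are monotone on the generator output", {
  cfg <- genome_sim_config(n_contigs = 1L, contig_length = 30000L,
                           n_planted_rflp = 0L, n_genes = 5L, seed = 404L)
  sim <- simulate_genome_pair(cfg)
  snps <- sim$variants[sim$variants$kind == "SNP", ][1:80, ]
  sm <- summarize_effects(snps, sim$gene_models, sim$genome,
                          covered_length = 30000L)
  expect_lte(sm$n_genes_nonsynonymous, sm$n_genes_with_cds_snp)
  expect_gte(sum(sm$region_counts), nrow(snps))  # multiplicity
})
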