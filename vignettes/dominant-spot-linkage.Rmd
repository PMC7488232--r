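---
title: "Mapping a dominant coat-spotting trait with restriction-site markers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a dominant coat-spotting trait with restriction-site markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotmap)
```

spotmap implements the analysis pipeline behind a classic candidate-gene
linkage design: two interfertile species (deer mouse stock BW, old-field
mouse stock PO) differ at about one variant per 68 bp; variants that
create or destroy restriction-enzyme recognition sites give cheap
gel-scorable CAPS/RFLP markers; and a backcross of an F1 carrier of a
dominant trait (here the *Dominant spot* allele, S, carried on the BW
haplotype) to the PO stock turns each marker into a linkage test. This
vignette documents the models, the tunable parameters, and the choices
made where the design was genuinely open.

## Restriction-site scanning

A recognition motif is an IUPAC string (e.g. `CRCCGGYG`). `scan_sites()`
reports a 1-based start position when the window matches the motif on the
forward strand or is matched by the motif's reverse complement — a site
is cuttable regardless of the strand it happens to be written on — and
palindromic motifs are reported once per position. Two deliberate rules:

* **N never matches**, including against degenerate motif positions.
  Assembly gaps are runs of N; letting them match would inflate
  genome-wide site counts and deflate average fragment sizes.
* **Overlapping matches are all reported.** Overlap handling belongs to
  digestion, not detection.

Internally the scanner is Biostrings pattern matching with the motif
expanded and the subject literal; the test suite checks it against a
per-position brute-force double-strand matcher on random sequences with
and without N.

For RADseq planning, `genome_site_stats()` summarizes an enzyme over a
genome of total length $G$: the site count $C$, the average fragment
$\bar L = \mathrm{round}(G/C)$, and the RAD marker yield $R = 2C$ (each
site is sequenced from both flanks). $\bar L$ is defined as assembly
length over site count — not sites-plus-contigs — which keeps
$C \cdot \bar L \approx G$ as an internal consistency law the tests
enforce. `rank_enzymes()` orders a panel by $|\bar L - \text{target}|$
with alphabetical tie-breaks. The built-in catalog holds the 30-enzyme
survey panel plus the marker enzymes StuI, MspI, KpnI and AciI, with
standard recognition sequences and top-strand cut offsets; an absent
offset defaults to mid-site, which affects only the cosmetic fragment
split, never the presence/absence logic markers rely on.

## Marker discovery and amplicon design

`find_rflp_variants()` compares, for every variant and enzyme, the
reference window of radius $|\text{motif}| - 1$ around the variant span
with its variant-applied counterpart. That radius is the smallest that
cannot miss an affected site: any site whose window overlaps the edit
starts within it. Site correspondence is computed through the coordinate
map of `apply_variants()` (deleted bases map to the preceding retained
base, flagged), so an indel that shifts — but preserves — downstream
sites is not miscalled. A variant may destroy a site for one enzyme and
create one for another, or both for the same enzyme; every effect is
reported, with no precedence.

`design_marker()` turns a candidate into a scorable assay. No published
rule fully determines the amplicon constraints, so the defaults are
explicit and configurable:

* amplicon length 200–600 bp — the working range for agarose genotyping
  and the envelope of the published marker set (213–526 bp);
* exactly one site for the diagnostic enzyme on the cut-bearing allele
  (a second constitutive cut makes the het pattern ambiguous); the
  search derives the feasible window range from the neighbouring sites
  and verifies each candidate window by digestion;
* the three genotype patterns — homozygote digests plus the heterozygote
  as their multiset union — must be pairwise distinguishable at a gel
  resolution of 20 bp.

When no window satisfies all three, a design failure with the reason is
returned rather than a degraded marker. Six-base cutters almost always
admit a design in random sequence; four-base cutters (AciI, MspI)
frequently do not, because a 200 bp window free of further sites is
rare — which is why the synthetic generator plants six-cutter sites by
default. Genotype calling (`call_genotype()`) is multiset matching with a
per-fragment tolerance (default 10 bp) and returns `no_call` unless
exactly one genotype matches; partial digestion is not modelled.

## Variant-consequence classification

`classify_region()` annotates each variant against every overlapping
transcript: exon/intron by containment; 5′/3′ UTR by exonic position
relative to the CDS span, strand-aware; splice donor/acceptor as the two
intronic bases abutting each exon boundary; splice region as intronic
bases 3–8 and exonic bases 1–3 from a boundary (the convention of the
mainstream annotation tools, configurable); upstream/downstream within a
5 kb flank of the transcript span; and intergenic as the exhaustive
fallback. One variant may carry several annotations, so category counts
exceed variant counts — rollups are per gene.

`coding_effect()` splices the CDS, applies the variant, and translates
both haplotypes with the standard genetic code (reverse-complemented for
minus-strand models). Length-preserving SNPs are classified by codon
comparison (silent, missense, nonsense, stop_lost, start_lost); indels
by length modulo 3 (in-frame vs frameshift). Variants straddling a CDS
boundary and CDS models whose length is not divisible by 3 are flagged
and skipped rather than guessed. The tests validate SNP classification
against an independent translate-and-compare oracle (seqinr) and check
minus-strand behaviour by full mirror construction. No attempt is made
to reproduce a full annotation grammar (regulatory motifs,
canonical-transcript selection, selenocysteine), and genome-scale
published category counts are out of reach without the external
assembly; the classifier is validated on synthetic ground truth instead.

## The synthetic genome pair

`simulate_genome_pair()` emulates the divergence structure the pipeline
was built for: i.i.d. reference bases; variants placed as a Bernoulli
process at one per 68 bp so the count is Binomial; a class mix of 89.3%
SNPs and 5.35% each insertions/deletions of 1–8 bp (the proportions of
the genome-wide variant classes in the motivating comparison); planted
enzyme-site-disrupting SNPs (a concrete instantiation of the motif is
written into the reference, then broken in the alternate allele, with
re-scanning to confirm no residual site); and non-overlapping gene models
with complete CDSs. Deliberate simplifications: uniform base
composition, no mutation clustering, no repeats, and adjacent variants
are allowed except where a deletion would overlap its neighbour (its
length is capped by the gap, demoted to a SNP when there is no room).
Passing tests on this generator demonstrate correctness of the
*machinery* — scanning, window logic, coordinate maps, translation — not
realism of genome structure; conclusions about real assemblies (e.g.
actual per-enzyme site counts) require the real sequence.

## The simulated backcross

`simulate_backcross()` models the cross design: F1 animals heterozygous
BW/PO everywhere, carrying S on the BW haplotype; N2 offspring receive a
PO gamete and a recombinant F1 gamete. Linked markers recombine under
the Haldane map function (no interference — at the marker densities used
here interference is immaterial); modifier loci are unlinked. Defaults
are the study conditions: 6 F1, 125 N2, two modifier loci, S/S
embryonic-lethal (exercised by `simulate_intercross()`, where a quarter
of conceptuses are flagged resorbed).

**Penetrance and rescue.** The observed deficit of spotted N2 (46 of
125 where 62.5 are expected) is compatible with either partial lethality
of `S/+` on the mixed background or phenotypic rescue by modifiers; the
data cannot distinguish them, so both are config switches. The default
regime implements rescue: a carrier homozygous PO at *every* modifier
locus shows no spot with probability `rescue_prob = 1`. With two
modifiers this removes a quarter of carriers, giving an expected spotted
fraction of 3/8 — 46.9 of 125, matching the observed 46.

**Spot size.** Sizes are lognormal. The log-scale location decreases
linearly with the number of PO modifier alleles (het = 1, homozygous =
2), anchored so that the zero-PO-allele background reproduces
77.6 ± 36.6 mm² and the F1 configuration (heterozygous at all k
modifiers) reproduces 3.75 ± 1.56 mm²; the log-scale sd interpolates
between the same anchors. The lognormal-with-additive-shifts form is a
modelling invention; only its two calibration anchors are empirical.
"Resembles the F1 parent" is defined as a spot size inside the central
95% band of the F1 size distribution — the notion is not defined
precisely in the source analysis, so the generator defines it, and the
inference layer takes the resemblance count as given input, keeping the
arbitrary threshold out of the statistics.

**A selection-bias property worth knowing.** Under the default rescue
regime, the rescued carriers are exactly the all-PO-modifier class, so
among *spotted* animals the three remaining modifier configurations
renormalize and the fraction resembling the F1 concentrates near 1/3
rather than $2^{-2}$ — strikingly close to the observed 17/46 = 37%. The
modifier-count statistic, however, assumes spotted animals are an
unbiased sample of carriers. Parameter-recovery checks therefore run the
generator with `rescue_prob = 0` (complete penetrance), where the
resemblance fraction is $2^{-k}$ by construction; with rescue on, the
same statistic is biased toward smaller k. This is a property of the
design, not a bug in either component, and it is one reason the original
analysis could not separate one from two modifiers.

## The statistics layer

All goodness-of-fit tests are Pearson chi-square with df = classes − 1
and no continuity correction. Expected counts follow the whole-animal
convention: every class but the last is rounded half-up, the last is the
complement, so expectations sum to N exactly (e.g. 63/62 from 125 under
1:1). This is the only convention consistent with the full set of
printed statistics the package reproduces (46; 9.25; 1.29; 3.13; 2.82;
23.19); continuity correction, in particular, is ruled out by the 9.25
and 23.19 values. The unrounded statistic is always reported alongside,
and two edge rules apply: a class with zero *raw* expectation is an
error, while a tiny-N rounding that would zero a class falls back to the
unrounded expectations.

`exclusion_test()` excludes a marker when at least 2 affected animals
are homozygous PO (default; "multiple" observations protect against a
single genotyping artefact, and the threshold is configurable down to
the strict genetic rule of 1). A marker fully cosegregating with the
trait is never excluded at any n. With ~46 affected animals, a marker 1
cM from the causal locus stays linked in about 93% of crosses
(P[Bin(46, 0.0099) ≤ 1]); the tests assert that binomial expectation.
`linked_interval()` brackets the run of markers heterozygous in all
affected animals by the nearest flanking recombinant markers, flagging
open ends.

`modifier_inference()` tests the resemblance count against
$2^{-k} : 1 - 2^{-k}$ for each candidate k and retains the values not
rejected at α = 0.05 — the level implied by the published reject/retain
pattern (p = 1.5 × 10⁻⁶ rejected; 0.077 and 0.093 retained).

`welch_from_summary()` computes Welch's t from (mean, sd, n) summaries
with Welch–Satterthwaite degrees of freedom; the integer df is reported
as the floor of the real value while the p-value uses the unfloored df.
For the spot-size comparison this yields t = 8.34, df 27.34 → 27,
p ≈ 5.4 × 10⁻⁹.

## Problem sizes and numerical choices

The test suite validates the scanner and classifier on 5–100 kb
synthetic sequences (brute-force oracles are quadratic-ish pure R, and
these sizes already exercise every code path), marker recovery on 25–30
kb genomes with 8–10 planted sites, and the cross pipeline on 500
replicates of the 125-animal design; the whole suite runs in about two
minutes. Determinism: every generator is a pure function of (config,
seed). Tolerances: genotype calling defaults to ±10 bp per fragment
against a 20 bp design resolution, so the simulated ±5 bp gel noise
calls correctly in >99% of gels; p-values are checked against
independent distribution routes (normal-square for df = 1, numeric
integration otherwise) to 1e-10.

## Known limitations

* No dCAPS (mismatch-primer) design, primer thermodynamics, or
  band-intensity modelling; primers are carried as opaque fixtures.
* No methylation sensitivity or star activity in digestion; single-
  enzyme RAD statistics only (no ddRAD two-enzyme windows).
* The consequence classifier is deliberately simplified; its counts are
  not claimed identical to any full annotation tool's multiplicity
  semantics.
* The backcross simulator is a single-chromosome-plus-unlinked-loci
  model: no X-linkage, no interference, no population structure.
* No lift-over between assembly versions; all coordinates are local to
  the supplied FASTA.
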