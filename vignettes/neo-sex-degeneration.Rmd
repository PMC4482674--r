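---
title: "Methods: measuring early neo-Y degeneration, allelic expression and chromatin state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring early neo-Y degeneration, allelic expression and chromatin state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neosex)
```

## The scientific setting

When an autosome fuses to a sex chromosome, the autosomal arm attached to the
Y becomes male-limited and stops recombining: a neo-Y. From that moment its
genes accumulate degenerative mutations, its alleles can be silenced, and its
chromatin can shift toward heterochromatin, while the neo-X may evolve dosage
compensation. In a young system (under a million years) all of these processes
are incipient and must be measured from subtle signals: heterozygosity present
only in males, slightly skewed allele-specific read counts, and modest shifts
in ChIP enrichment. This package implements that measurement pipeline for a
Drosophila-style system in which a small, heterochromatin-like dot chromosome
has fused to the sex chromosomes, and pairs it with a seeded simulator that
generates every input with recorded ground truth, so each inference step can
be validated against planted answers.

## Fixed differences from two sequenced individuals

With one sequenced male and one sequenced female, a site heterozygous in the
male but homozygous in the female is the signature of a fixed neo-X/neo-Y
difference: males carry one neo-X and one neo-Y allele, females two neo-X
alleles. `filter_variants()` first applies the variant-quality and depth
filters (keep `qual >= 30`, `depth >= 5`; boundary values are kept because
the discard rule is "quality < 30 or depth < 5"). `classify_sites()` then
partitions sites into `male_specific` (putative fixed differences),
`shared_het` (segregating polymorphism, excluded), `female_het` (used to
estimate how much polymorphism contaminates the male-specific set), and a
non-heterozygous remainder. Because the sequenced line is inbred but not
perfectly so, some "fixed" differences are actually segregating; a
polymorphic site has a one-half chance of appearing male-specific, so the
contamination fraction is estimated as
`(n_female_het / 2) / n_male_specific`. With the counts the pipeline is scaled
to (16,977 male-heterozygous vs 496 female-heterozygous sites) this is about
1.5%, small enough to leave divergence-based inferences intact. An optional
quantile-based per-sex quality recalibration (`quality_recalibration_cutoff()`)
is provided for unequal male/female coverage, but is disabled by default
because no principled second-round formula exists.

`build_neo_y()` applies the male-specific variants to the reference (neo-X)
sequence to reconstruct the neo-Y: SNPs substitute in place, indels (VCF
anchor-base convention, left-aligned) shift downstream coordinates, and a
position map allows any reference interval to be projected onto the neo-Y.
Overlapping variants are rejected rather than resolved: callers do not emit
them, and silent resolution would corrupt ground-truth tests.
`recover_variants()` is the inverse operation — an exhaustive two-cursor
comparison of the two sequences with an exact downstream anchor (20 bp by
default) — and is deliberately independent of `build_neo_y()`, so applying a
variant set and recovering it is a genuine round trip.

## Calling degenerate genes

`project_and_apply()` splices each gene's strand-oriented CDS from the
reference and applies the variants that fall in exons (reverse-complemented
for minus-strand genes); intronic variants leave the CDS untouched, and an
indel straddling an exon boundary flags the gene unresolvable instead of
being silently truncated. `classify_orf()` then calls:

* **FRAMESHIFT** — at least one coding indel of length not divisible by 3;
* **PTC** — translation of the neo-Y CDS reaches a stop codon strictly before
  the expected terminal codon;
* **PTC_AND_FRAMESHIFT** — both.

Three design choices were genuinely open. First, the expected terminal codon
index is the reference codon count adjusted by the net length of in-frame
indels, so a 3n indel that merely moves the original stop earlier is not a
premature stop. Second, a gene whose frame is restored downstream by
compensating indels is still FRAMESHIFT — the intervening peptide is
scrambled — with a separate `frame_restored` flag. Third, a premature stop is
called at any position, even the penultimate codon; `truncation_fraction`
(the fraction of the reference protein retained before the stop) lets users
impose stricter positional definitions downstream. Start-codon loss is a
separate flag, not folded into PTC. `summarize_status()` reports per-category
counts and the non-functional proportion; on the package's default
study-scale fixture (86 genes, 50 of them carrying planted degenerative
mutations) it reproduces 50/86 = 58.1% non-functional.

## Dating the divergence

"Silent sites" are defined conservatively as 4-fold degenerate third codon
positions — positions where any substitution leaves the amino acid unchanged —
identified from the standard nuclear code and validated in the tests against
a brute-force mutate-and-translate oracle. `silent_divergence()` counts
differences at positions 4-fold degenerate in *both* alleles. Under
neutrality divergence accrues at twice the mutation rate, so
`estimate_age()` reports `t_generations = d / (2 * mu)` with the default
Drosophila rate `mu = 5e-9` per bp per generation, and
`t_years = t_generations / gen_per_year` at 10 generations per year. Both
scales are reported explicitly because shorthand accounts often quote the
generations figure as years; at the median divergence of 0.84–0.85% the
estimate is 840,000–850,000 generations, i.e. under a million generations,
and 84,000–85,000 years under the default generation time. Medians, not
means, summarize per-gene divergence throughout.

`ng86_kaks()` provides a pairwise Ka/Ks by the Nei–Gojobori (1986) counting
method — fractional site counting per codon, pathway averaging for multi-hit
codons (pathways through stop codons excluded when avoidable), Jukes–Cantor
correction skipped and flagged when a raw proportion reaches the p >= 0.75
ceiling. It is labelled "pairwise NG86" everywhere: it is a desk-scale
statistic, not a likelihood branch model, and substitutions to stop codons
are treated as nonsynonymous. Codon-usage bias is summarized by Fop (fraction
of optimal codons among synonymously variable codons), CBI
(`(Nopt - Nrand) / (Ntot - Nrand)` with `Nrand` the count expected under
uniform synonymous usage) and CAI (geometric mean of relative-adaptiveness
weights). The optimal-codon table is an explicit input;
`optimal_codons_from_usage()` derives one as the most frequent codon per
amino-acid family in a reference gene set, which is what the pipeline uses on
simulated data rather than shipping a species table of uncertain provenance.

## Allele-specific expression with DNA normalization

Reads overlapping male-specific SNPs can be assigned to the neo-X or neo-Y
allele. Mapping bias would distort a naive neo-X:neo-Y RNA ratio, but the
same gene's DNA-seq reads from the same male must come from exactly one copy
of each allele, so the DNA ratio absorbs the bias. `allelic_bias_test()`
therefore tests the 2x2 table `[[dna_x, dna_y], [rna_x, rna_y]]` with a
two-sided Fisher exact test (sidedness is a package choice; the direction of
each effect is recoverable from the ratio) and reports the normalized effect
`log2((rna_x/rna_y)/(dna_x/dna_y))`, which is 0 exactly when the odds ratio
is 1. A pseudocount of 0.5 enters all four cells only when some cell is zero,
and only for the ratio — the exact test always uses raw counts. Genes with a
zero DNA count on either allele are excluded (normalization undefined) and
reported. Significance for the headline count uses the raw p at alpha = 0.05,
matching the field's convention for this analysis; Benjamini–Hochberg
adjusted values are reported alongside for modern use.

Expression level is RPKM; `active_cutoff()` separates transcribed genes from
intergenic background at the crossing point of the two Gaussian kernel
density estimates (Silverman's rule-of-thumb bandwidth, common grid, smallest
density-equality point between the two global modes). Non-separable input
falls back, with a warning, to the reference default log10 RPKM = 0.65.
`sex_bias()` compares combined neo-X+neo-Y male expression with female
expression (unbiased band: fold difference < 1.5) and exposes per-allele
male/female ratios — under two female neo-X copies and no compensation, the
male neo-X allele runs at half the female level, which is the diagnostic the
pipeline checks for incipient dosage compensation. `correlate_bias()` is a
tie-corrected Spearman rank correlation for relating allelic bias to sex
bias.

## Chromatin profiles

`gene_enrichment()` computes per-gene log2 ChIP/input enrichment over the
gene body plus 1.5 kb flanks, normalized by track totals with a pseudocount
of 0.5 reads per region (the pseudocount value is a package choice for
log-ratio stability). `allele_enrichment()` does the same from
allele-resolved site counts, normalizing ChIP against input only — no further
DNA correction, since the input control already absorbs mapping bias — with
totals over both alleles so a genuine allelic ChIP excess is retained.

Metagene profiles scale every gene body to 20 equal-fraction bins plus five
300-bp flank bins per side (counts configurable; the scaling is fixed by the
method, the bin numbers are not), strand-oriented so bin 1 is 5'.
`bound_cutoff()` derives the bound/unbound threshold as the density-crossing
point between the bin-enrichment distributions of a target gene group and
the background groups — the same machinery as the expression cutoff, applied
per scaled bin — and `metagene_profile()` reports, per group and bin, the
fraction of genes at or above the threshold. Group contrasts (e.g. neo-Y vs
neo-X alleles, silencing-mark target groups vs background) use two-sided
Wilcoxon rank-sum tests via `group_compare()`. Expression status for
grouping defaults to the neo-X allele's activity, with the neo-Y allele's
status available by flag, because the two conventions answer different
questions (compensation vs silencing).

## What the simulator emulates — and what it does not

`simulate_bundle()` generates, under one seed: valid gene models (ATG start,
single terminal stop, no internal stop, length divisible by 3, mixed
strands, introns, intergenic spacers); a neo-Y haplotype with silent
substitutions planted per-site at probability `silent_divergence_d` (default
0.0084), optional nonsynonymous substitutions (rejection-sampled never to
create stops), degenerative mutations in designated target genes, and
neutral intergenic/intronic indels; per-site DNA/RNA/ChIP/input allele
counts (Poisson depth, binomial or beta-binomial split — `dispersion` is the
intraclass correlation); expression counts from two separable log10-RPKM
normal components (gene mean 1.5, intergenic mean -0.5, sd 0.5 — chosen so
the mixture is separable but overlapping, like real density plots); and
binned coverage tracks with group-specific enrichment and an optional
3'-increasing gradient. Defaults are the study conditions the pipeline is
scaled to: 86 genes, mean CDS 1.5 kb, 50 pseudogene targets, a 2-fold neo-X
expression bias (a moderate value within the observed range of allelic
skews).

Two generator details exist purely to keep ground truth unambiguous, and are
worth knowing when interpreting tests. Planted indels are rejection-sampled
to be left-aligned with a detectable anchor mismatch, so exhaustive sequence
comparison recovers exactly the planted representation; and frameshift
indels are placed near the 3' end of the CDS and resampled until the shifted
tail introduces no premature stop, so a FRAMESHIFT label never silently
becomes PTC_AND_FRAMESHIFT. Real data are messier on exactly these margins.
The simulator also does not emulate read-level artefacts: no sequencing
error, no mapping bias beyond a single configurable DNA-ratio skew, no
overlapping genes, no alternative isoforms, and polymorphism appears only as
planted heterozygous SNP sites. Passing recovery tests therefore demonstrate
that the inference machinery is correct, not that it is robust to every
failure mode of real libraries.

## Numerical and reproducibility choices

All coordinates are 1-based inclusive internally (the R/Bioconductor
convention), converting only at the BED-like coverage-track boundary
(0-based half-open). Every stochastic step draws from the R RNG seeded from
`cfg$seed` plus a small fixed per-operation offset, so each generator
operation is individually deterministic and a whole bundle is byte-identical
across runs. KDE cutoffs interpolate the equality point linearly between
grid nodes (1024-point grid), which makes them deterministic and
translation-equivariant to well under the grid spacing. Fisher tests,
Wilcoxon tests, Spearman correlations and BH adjustment are delegated to
base R's `stats`; the exact tests are cross-checked in the test suite
against an independent hypergeometric enumeration and an exhaustive
permutation oracle.

Problem sizes in the test suite are the package's own validation scale:
hand-built toy genes for every exact ORF case; 86-gene study-scale fixtures
for the degeneration count; a 100-gene, 3.6-kb-CDS fixture giving over
50,000 silent sites for divergence recovery; 500-gene fixtures for the
type-I calibration and power checks of the allelic test; 200–250-gene
fixtures for metagene properties; and a 1,000-variant round trip for the
reconstruction machinery.

## Known limitations

The pairwise NG86 Ka/Ks is not a substitute for branch-model likelihood
estimates and is reported only as a constraint summary. The
polymorphism-contamination estimator is a reconstruction of a quantity whose
exact published formula is not stated; it reproduces the published value and
its halving logic is documented above. The density-crossing cutoffs assume
unimodal components; heavily multimodal enrichment distributions will
trigger the fallback default. Genes shorter than the body-bin count are
excluded from metagene profiles rather than interpolated. The pipeline
consumes variant calls and count tables; it does not align reads or call
variants from BAMs.

## A worked run

```{r example, eval = FALSE}
cfg <- default_sim_config(seed = 1)          # 86 genes, 50 targets, d = 0.0084
report <- run_pipeline(pipeline_config(sim = cfg))
print(report)
```

The printed report carries the male-specific site count, the polymorphism
contamination, the non-functional gene proportion, median and pooled silent
divergence with the age estimate in generations and years, the number of
genes with significant neo-X/neo-Y expression bias, and the two
distribution-derived cutoffs. `scripts/acceptance.R` recomputes the pooled
silent divergence and the degenerate-gene count from fresh seeded fixtures.
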