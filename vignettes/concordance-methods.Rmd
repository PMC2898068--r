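---
title: "Methods: genome/transcriptome SNV concordance and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome/transcriptome SNV concordance and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(snvconcord)
library(dplyr)
```

## The question the package answers

When the same tissue is sequenced twice — once as genomic DNA (gDNA) and
once as reverse-transcribed mRNA (cDNA, i.e. RNA-Seq) — both experiments
can call single-nucleotide variants (SNVs) in exons, and the two call sets
can be compared. The comparison is asymmetric: the gDNA set acts as the
reference truth.

* **Sensitivity** = TP / (TP + FN): the fraction of genome-identified
  exonic SNVs that RNA-Seq recovers. In standard terms this is a recall.
* **Specificity** = TP / (TP + FP): the fraction of RNA-Seq SNV calls
  confirmed in the genome. Despite its name, this is a precision; the
  package keeps the domain's vocabulary but documents the distinction.

Both quantities are reported as `NA`, never 0, when their denominator is
empty.

A pair of calls can be matched at two stringencies. In **position** mode,
sharing a (chromosome, position) suffices. In **genotype** mode the
unordered allele pair must also agree; a position-matched pair with
discordant genotypes then counts as one false positive *and* one false
negative — the genomic variant was missed and a wrong variant was
asserted — which preserves the conservation laws

* TP + FN = number of gDNA calls,
* TP + FP = number of cDNA calls,

in both modes. The tallying is configurable (`mismatch_policy`) for users
who prefer other conventions, but the default keeps the confusion matrix
additive.

## Why RNA-Seq disagrees with the genome

Four mechanisms dominate, and each has a first-class representation in the
package:

1. **Expression-limited detection.** A heterozygous variant in a
   transcript expressed at depth $d$ is seen iff at least 3 reads carry
   the alternate allele; for a balanced heterozygote that probability is
   the binomial tail $P(\mathrm{Bin}(d, 1/2) \ge 3)$. Silent genes are
   undetectable no matter how real the variant. `stratify_by_expression()`
   recomputes the metrics in log-spaced expression bins (percent of the
   most expressed transcript; 4% is the conventional "well expressed"
   threshold and falls exactly on a bin edge of `make_log_bins()`).
2. **Allelic imbalance.** Some heterozygous loci express one allele almost
   exclusively. The cDNA then looks homozygous (or the variant vanishes
   entirely when the reference allele dominates).
   `zygosity_breakdown()` partitions position-matched pairs into
   het→hom, hom→het, matching, and complete-mismatch categories.
3. **Paralog misalignment.** Reads transcribed from one locus can align
   to a homologous copy, planting non-reference bases there.
   `partition_by_paralog()` contrasts genes with and without annotated
   paralogs.
4. **Splice-boundary artifacts.** Near exon ends, read termini crossing a
   splice junction mimic substitutions; the QC screen removes calls whose
   alternate support is carried more than 20% by read-end bases.

## The QC screens

`filter_params()` encodes the screens applied before any comparison:
minimum SNP quality (30 for cDNA, 20 for gDNA), at least 3 reads
supporting the non-reference allele, a maximum site depth (10^6 cDNA,
10^7 gDNA), and the end-of-read rule for cDNA only. The pass set is a pure
conjunction of per-call predicates, so filtering is idempotent and
order-independent; each removed call is attributed to the first rule it
fails, in a documented order, for reporting. Threshold inclusivity is
explicit and configurable: a call exactly at a minimum passes by default.

Coordinates are 1-based inclusive everywhere inside the package; BED and
bedGraph inputs (0-based half-open) are converted at the boundary, in
`read_exon_annotation()` and `read_depth_track()`, and nowhere else.

## The simulator

Real studies of this kind hinge on hundreds of millions of reads, which a
desk-scale package cannot reproduce. Instead, `simulate_truth()` and its
companions generate a fully ground-truthed synthetic study in which reads
are never materialised: per-site read depths and allele supports are drawn
directly from the distributions that reads would induce.

### Design

* **Layout.** `n_genes` single-transcript genes tiled on one synthetic
  chromosome; exon counts are 1 + Poisson, exon lengths Gamma-distributed
  (shape 4) with a 30 bp floor.
* **Expression.** A two-component lognormal mixture on the percent-of-max
  scale: a silent component (fraction 0.47 of genes, centred far below
  detectability) and an expressed body (`sdlog` 0.94), rescaled so the
  maximum is exactly 100. The mixture reproduces the empirical situation
  in which roughly half the genome is effectively untranscribed in any
  one tissue.
* **Depth calibration.** Per-lane site depth is Poisson with rate
  $k \cdot \mathrm{expression}$; the constant $k$ is fixed so that the
  *median expressed exon* reaches 126 reads/base at the full lane count
  (8 lanes), matching the scale of a deep RNA-Seq experiment. gDNA depth
  is Poisson with mean 24.
* **Variants.** Planted at rate 0.0016 per exon base, 35% homozygous.
  Heterozygotes draw cDNA alternate support as Binomial(depth, 1/2)
  unless they carry an allelic-imbalance state (probability 0.2, half
  toward each allele), in which case the alternate probability is near 0
  or 1.
* **Paralog false positives.** Each paralog-flagged exon hosts
  Poisson(0.5) misalignment sites. A site draws a *source* locus
  expression from the study's own expression distribution and a
  misalignment fraction uniform on (0, 0.5); misaligned reads arrive as
  Poisson(fraction × k × source expression) per lane, all carrying the
  non-reference base, *adding* to the exon's own depth. This additive
  source-driven construction is what produces the observed phenomenology:
  artifact calls pile up at depth extremes (silent target, weak source →
  shallow nearly-pure-alternate piles; strong source → enormously deep
  piles), so an intermediate depth window raises specificity, and
  specificity rises with target expression because genuine calls dilute a
  roughly constant artifact load.
* **End-of-read artifacts.** Planted within 3 bp of exon boundaries on
  covered exons; their alternate-supporting reads are end-of-read bases
  with probability 0.8, so the 20% end-fraction screen removes most.
* **Sequencing error.** Per-base error 0.001; error-driven calls require
  three same-base errors at one site, giving the closed-form per-base
  intensity $3 \cdot P(\mathrm{Bin}(d, e/3) \ge 3)$ used for both call
  sets.
* **Known-site membership.** Each planted variant enters a dbSNP-like
  position list with probability 0.90, each planted artifact with
  probability 0.23 — so the recovery of these rates by
  `known_site_rates()` is a direct check of the classifier.
* **Lane snapshots.** Per-lane draws are made once and accumulated, so
  the cumulative snapshots (1 lane, 2 lanes, …) are *nested*: a call
  never disappears and depth never decreases as data accumulate.
  `lane_accumulation_curve()` consumes them directly.

### Quality proxy

Callers emit a Phred-like SNP quality; the simulator uses a deterministic
monotone proxy, `15 × alt × min(1, 2.5 × alt/depth)` plus small uniform
noise. It grows with alternate support and is discounted when a few
alternate reads sit under a deep reference pile — the regime in which
consensus callers are least confident. The proxy is not a calibrated
likelihood; tests that need exact detection probabilities therefore use
the raw ≥3-alternate-reads gate, whose binomial tail is closed-form.

### Limitations

The simulator is a study-shaped null model, not a sequencing emulator:
no read-level alignment, no mapping-quality structure, no
position-in-read error profiles, one transcript per gene, uniform
isoform structure, and independence across sites. Its purpose is to give
every pipeline stage a ground truth with known parameters and the right
directional behaviour, not to imitate any particular instrument.

## A worked run

```{r pipeline}
cfg <- simulation_config(n_genes = 500, seed = 42)
truth <- simulate_truth(cfg)
gdna <- simulate_gdna_callset(truth)
sim <- simulate_cdna_callset(truth)

gdna_qc <- restrict_to_exons(filter_calls(gdna, filter_params("gDNA")), truth$exons)
cdna_qc <- restrict_to_exons(filter_calls(sim$calls, filter_params("cDNA")), truth$exons)

cls <- classify_calls(gdna_qc, cdna_qc, "position")
glance(cls)
```

```{r strata}
stratify_by_expression(cls, truth$expression)
filter_by_depth_window(cls, 50, 1200)
partition_by_paralog(cls, truth$genes)
known_site_rates(cls, truth$known_sites)
```

```{r plot, fig.width = 6, fig.height = 4}
library(ggplot2)
autoplot(stratify_by_expression(cls, truth$expression))
```

## Numerical conventions

* Genotypes are canonical sorted unordered pairs (`allele1 <= allele2`);
  IUPAC ambiguity codes are decoded at read time and never stored.
* Duplicate positions within one call set are collapsed at read time:
  highest SNP quality wins, ties break lexicographically by genotype.
* The lower median (`sort(x)[ceiling(n/2)]`) is the default for coverage
  summaries so the reported value is an actually observed exon coverage;
  the interpolating median is available as an option.
* All randomness flows from a single integer seed in
  `simulation_config()`; derived seeds for the two call sets are
  `seed + 1` and `seed + 2`, kept below 2^31.
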