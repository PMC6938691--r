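---
title: "Hybrid filter/random-forest quality control of sequencing variants"
author: "VariantForest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid filter/random-forest quality control of sequencing variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VariantForest)
```

## The problem and the model

Joint genotyping of a sequenced cohort yields millions of candidate
variant sites, a non-trivial fraction of which are artifacts: sites in
poorly mappable or extreme-GC regions, sites genotyped from too few reads,
or caller errors. Two QC traditions exist. *Filtering* removes sites whose
summary statistics cross fixed thresholds — simple and interpretable, but
every threshold is a cliff: a site with 5.1% missingness dies while one at
4.9% survives, and the thresholds must be re-tuned per study.
*Classification* (e.g. Gaussian-mixture recalibration against external
truth resources) generalizes better but needs curated reference call sets,
which bias the result toward known, common variation and do not exist for
many species.

`VariantForest` combines the two so that each covers the other's weakness.
Stringent filters are used only where they are unambiguous: a site must
pass *all* strict "good" bounds to be labeled HIGH at the filter stage,
and fails *any* lenient "bad" bound to be labeled LOW. The sites in
between — the gap the filtering tradition handles worst — are labeled by a
random forest trained on the filter-stage HIGH/LOW sets themselves, so no
external truth resource is ever consulted. The final HIGH set is the union
of filter HIGH and predicted HIGH; the final LOW set likewise; the two
always partition the input. SNVs and indels run as fully separate streams
(their error profiles and attainable quality differ substantially), each
with its own training set and forest.

## Filter statistics

Four per-site statistics drive the filter stage.

* **Genotype missing rate** — missing alleles over `2n`. A half-missing
  genotype (`./1`) is treated as fully missing by default; the
  `halfCalls = "partial"` policy instead counts one missing allele (the
  field has no consensus here, so the choice is a flag).
* **Mendelian error rate** — over pedigree trios with all three members
  genotyped, the fraction whose child cannot be formed by drawing one
  allele from each parent. Computed for autosomes only; sex chromosomes
  and mitochondria return `NA` rather than applying wrong hemizygote
  logic. Without a pedigree the statistic (and its bounds) are simply
  absent.
* **HWE exact p-value** — the biallelic exact test conditional on allele
  counts, implemented by the standard stable recurrence over heterozygote
  counts, summing the null probabilities of every heterozygote count at
  most as probable as the observed one. No mid-p correction is applied
  (the plain test is the default of the widely used implementations this
  follows). Multi-allelic sites pool all alternate alleles into one
  class: the test is defined biallelically, and ref-vs-non-ref pooling
  matches the semantics ABHet already uses.
* **ABHet** — reference reads from ref/alt heterozygotes divided by all
  reads from those samples, *pooled* across carriers rather than averaged,
  so deeply sequenced samples carry proportional weight. Alt/alt
  heterozygotes (1/2) are excluded: reference balance is undefined for
  them, and allele balance generally misbehaves on multi-allelic sites.
  On chromosome X only samples recorded female in the pedigree enter the
  pool (hemizygous males would bias it); with no pedigree, all samples.

An `NA` statistic can never push a site into LOW; whether it can block
HIGH is governed by an explicit NA tolerance (default 0: any `NA` among
good-bound statistics sends the site to the classifier instead). This
keeps the partition property — every site gets exactly one final label —
while never letting absence of evidence condemn a site.

### Default thresholds

The defaults are deliberately stricter on the good side than the
GWAS-typical cut-offs (≤ 5% missing, HWE p ≥ 1e-4, ABHet within
0.25–0.75), because the HIGH/LOW sets become training labels and should be
unequivocal: good requires missing ≤ 0.01, ME ≤ 0.01, HWE p ≥ 1e-2, ABHet
∈ [0.45, 0.55]; bad triggers at missing ≥ 0.05, ME ≥ 0.05, HWE p ≤ 1e-6,
ABHet at or outside [0.25, 0.75]. Good bounds are inclusive intervals, bad
bounds inclusive triggers, and a validator guarantees the good interval
lies strictly inside the bad one so no value can satisfy both. All bounds
are overridable, and additional user-supplied per-variant statistics
participate under the same semantics. As a calibration aid,
`partitionReport()` warns when the filter-stage low-quality fraction falls
outside 4–16%: far fewer and the forest has too few negative examples;
far more and the "unequivocally bad" premise is broken.

## Classifier

Seven features, in a fixed canonical order: mean, population SD (divide by
`n`; the classifier is insensitive to the `n` vs `n−1` choice, but tests
need one answer) and outlier ratio of DP and of GQ, plus window GC
content. The outlier ratio is the fraction of samples strictly below a
dataset-wide lower-quartile threshold, pooled over every non-missing
per-sample value on one calibration chromosome (default `"1"`,
configurable — one chromosome is an efficiency choice, not a requirement).
The quartile uses linear interpolation between order statistics (the
`type = 7` default of mainstream numeric stacks); the rule is fixed and
documented because reasonable stacks disagree. GC content is computed on
fixed 1-kb windows tiling each chromosome from its first base,
`(G + C) / (A + C + G + T)` case-insensitively with other letters excluded
from both numerator and denominator, and a site inherits the value of
window `floor((pos − 1)/1000)`.

Training balances the classes by downsampling the majority uniformly
without replacement to the minority size — normally HIGH vastly outnumbers
LOW, giving a set twice the LOW count; when LOW happens to be the majority
the same rule downsamples it instead, preserving the balanced contract.
The forest uses 50 trees (past ~50 the accuracy gain no longer pays for
the time) with the `randomForest` package defaults for the per-split
feature count, depth and leaf size; those defaults, the feature order, the
training-set feature medians and the seed are all frozen into the
serializable model so predictions reproduce exactly across sessions. A
site is predicted HIGH iff its probability exceeds the threshold
*strictly* (default 0.5; ties go to LOW). Sites with an `NA` feature at
prediction time are imputed with the training-set median of that feature
and flagged — dropping them would break the partition property.

## The synthetic study

The generator exists so that every stage, invariant and acceptance
property runs with no download, and its defaults *are* the study
conditions: 20 trio families (60 samples, echoing a family-based design at
desk scale), 20,000 variants with 10% planted bad, two 600-kb autosomes
with a 0.3→0.7 GC gradient, deep balanced sequencing for good sites
(DP ~ Pois(35), GQ ~ N(90, 8), ABHet 0.5, 0.2% missingness) versus
shallow, overdispersed, skewed sequencing for bad ones (DP ~ NB(μ = 12),
GQ ~ N(30, 20), het AD drawn at 0.8 reference fraction, 8% missingness).
Founders draw genotypes at Hardy–Weinberg equilibrium given a per-site
allele frequency ~ U(0.02, 0.5); children inherit one allele per parent;
bad sites then receive post-transmission single-allele flips at rate 0.3.
That one mechanism produces *correlated* error signals — Mendelian
errors, chip discordance (the microarray extract copies pre-error truth
genotypes) and genotype-frequency distortion — the way real calling
errors do. One consequence worth noting: a flip frequently leaves a trio
Mendel-consistent, so the realized trio ME rate of bad sites is ≈ 0.17 at
flip rate 0.3, and the generator's self-consistency tests check direction
and plausible magnitude, not the naive flip rate. Good SNVs draw
transition alternates two thirds of the time (the genome-wide Ti/Tv ≈ 2
expectation); bad SNVs draw uniformly, depressing their Ti/Tv toward 0.5
as false positives do in real data.

What the generator does *not* emulate: linkage disequilibrium, mappability
structure, strand bias, batch effects, indel length spectra beyond 1 bp,
or reference errors. Passing the recovery tests therefore demonstrates
that the machinery is correct and that separable quality signals are
recovered — not that the default thresholds are optimal for any particular
real cohort.

## Numerical and degenerate-case choices

* The HWE recurrence starts at the modal heterozygote count and normalizes
  at the end, which is numerically stable to n in the thousands;
  configurations whose probability is within a 1e-7 relative tolerance of
  the observed one are included in the tail, following the reference
  implementations. Monomorphic sites and single-carrier sites return 1;
  all-missing sites `NA`.
* Per-sample DP falls back to the AD sum when FORMAT/DP is absent; if both
  are absent it is `NA`, never 0 — missingness must propagate, not
  masquerade as depth zero.
* Chromosome names are matched after stripping an optional `chr` prefix,
  consistently across VCF, FASTA, known-sites and microarray inputs.
* Multi-allelic sites stay un-split: one record, one label; SNV-ness
  requires the ref and every alternate to be single bases, and mixed
  SNV/indel sites go to the indel stream (conservative single
  assignment).
* Mitochondria are excluded from Ti/Tv by default (their substitution
  spectrum is atypical); sample-level Ti/Tv counts a site for an
  individual iff that individual carries at least one alternate allele.
* The end-to-end driver derives every random draw (training-set sampling,
  forest growth) from the single run seed, so reruns are byte-identical;
  the manifest records seed, config hash and per-stage counts and is
  written on failures too, naming the failing stage.

## Problem sizes

The test suite exercises the exact-test oracle on all genotype triples up
to 20 samples, the Mendelian oracle on all 27 trio configurations plus
1,000 random multi-trio sites, and the full pipeline on the 20,000-variant
default study; the acceptance script reruns that study end to end. These
sizes keep the whole suite in the minutes range on a single CPU while
leaving every statistic with enough data to be non-degenerate.

## Known limitations

ABHet and the exact HWE test are pooled ref-vs-alt approximations on
multi-allelic sites; hemizygous Mendel logic is deliberately absent;
strand-flip resolution between array and sequencing alleles is out of
scope (mismatching sites are skipped with a warning); and the evaluation
module implements the core metric subset named above rather than an
exhaustive QC-metric catalogue, with a report schema that is extensible
by adding named entries.
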