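---
title: "Methods: tissue selectivity scoring, enhancer rules and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue selectivity scoring, enhancer rules and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissel)
```

## The model

`tissel` implements a rule-based analysis of tissue selectivity. The central
statistic is the **specificity measure (SPM)**: for gene $g$ with
replicate-averaged tissue expression vector $m_g \in \mathbb{R}_{\ge 0}^T$,

$$\mathrm{SPM}(g, t) = \frac{m_{g,t}}{\lVert m_g \rVert_2},$$

the cosine similarity between $m_g$ and the indicator vector of tissue $t$.
SPM is scale-invariant (normalization of the FPKM unit cancels), lies in
$[0, 1]$, and satisfies $\sum_t \mathrm{SPM}(g,t)^2 = 1$ for any gene with
nonzero expression. A gene expressed in exactly one tissue has SPM 1 there;
a uniformly expressed gene has SPM $1/\sqrt{T}$ everywhere. Raising one
tissue's mean strictly raises that tissue's SPM and lowers every other's,
so the statistic orders genes by concentration of expression, not by level.

The statistic is computed on **replicate-averaged** tissue means, not on
individual samples: the unit of analysis is the tissue, and averaging first
keeps unevenly replicated tissues from dominating the norm.

### Assumptions

* FPKM is a non-negative, roughly multiplicative expression measure;
  replicate variation is modelled (and simulated) as log-normal.
* Tissues are treated as exchangeable categories; no phylogeny or lineage
  structure among tissues enters the score.
* All-zero genes have no defined expression direction; their SPM is flagged
  undefined (`NA`) rather than silently propagated, and they are never
  called selective or preferential.

## Calls and thresholds

| Parameter | Default | Units | Role |
|---|---|---|---|
| `fpkm_min` | 1 | FPKM | abundance floor: pre-filter (max over tissues) and the selective call's target-tissue mean; inclusive |
| `spm_min` | 0.9 | — | selective threshold, inclusive |
| `preferential_band` | [0.7, 0.9) | — | preferential call; half-open so no gene is both |
| `tss_min_dist` | 3000 | bp | enhancer distance rule; strict `>` |
| `merge_gap` | 1000 | bp | enhancer merging; inclusive, transitive closure |
| `promoter_flank` | 2000 | bp | half-width of the TSS window, strand-agnostic extent |
| `intensity_quantile` | 0.25 | — | strong-peak cutoff; linear-interpolation quantile, strict `>` |
| `pseudocount` | 0.1 | FPKM | added before `log2` in all correlations |
| `basal_up`/`basal_down` | 5000/1000 | bp | basal regulatory domain around the TSS, strand-oriented |
| `max_extension` | 1e6 | bp | cap on domain extension toward neighbors |

Both selectivity thresholds are **inclusive** (a gene at SPM 0.9 with mean
FPKM 1.0 is selective); the preferential band is half-open. A gene at or
above `spm_min` that fails the abundance floor is `none`, not
preferential — the band describes an intermediate specificity, not a
consolation class for low-abundance genes.

Two readings were genuinely open and are resolved as follows, with the
alternative exposed as an argument:

* **"above the 25% quantile"** is read as *above the 25th percentile* of
  all peak intensities (keeping ~75% of peaks), computed with the standard
  linear-interpolation empirical quantile; `strong_peaks(q, strict)`
  exposes both the level and the strictness.
* The **expression condition** on coding genes (for the lncRNA
  sense-overlap filter) and on the conditioning gene (for conditioned
  correlation) uses `>= 1` FPKM, inclusive; the sample-QC gene filter uses
  strict `> 1`. Both thresholds are arguments.
* The sense-overlap filter counts coding genes expressed in **any** tissue
  (mean FPKM at/above the floor somewhere), not only in the target tissue;
  the caller controls this by passing whichever `expressed_ids` set it
  prefers.

## Interval semantics

Every interval in the package is **0-based half-open** (BED convention);
GTF input (1-based closed) is converted on read and reconverted on write.
The TSS of a `-` strand gene is its rightmost transcribed base
(`end - 1`). Distances between a peak and a TSS or another peak are
minimal gaps (0 when overlapping), so "more than 3 kb away" means a gap of
at least 3001 bp. "Within 1 kb" merging is inclusive at exactly 1000 bp and
applied transitively after the distance filter; tissue-uniqueness uses
any-overlap (a single shared base disqualifies). Promoter windows are
symmetric around the TSS and clipped at the chromosome start; TSS-centered
profiles are strand-flipped so bins run 5′→3′. Interval arithmetic is
delegated to `GenomicRanges`/`IRanges`; the test-suite re-derives each
operation with brute-force oracles (union–find merging, per-base profile
averaging, per-gene domain scans).

Enhancer–gene association mirrors the common basal-plus-extension rule:
each coding gene owns a strand-oriented basal region (5 kb upstream, 1 kb
downstream of the TSS) extended in both directions to the nearest other
gene's basal region, capped at 1 Mb from the TSS; an enhancer (or lncRNA
locus) is associated with every gene whose domain contains its midpoint.
Basal regions may overlap, so one element can associate with two genes.
Only the association geometry is implemented, not any enrichment test.

## The synthetic study

`sim_config()` defines the study conditions; `simulate_study()` generates
them. The generator emulates:

* a **22-tissue panel** (a target tissue plus 21 named fetal-like tissues)
  with **5 replicates** per tissue (~110 samples, matching the scale of a
  public multi-tissue compendium) — acceptance-style recovery checks use 3
  replicates, the minimum that still exercises averaging;
* **planted selective genes** whose noise-free tissue means hit an exact
  target SPM: the target tissue gets mean $m$ and every other tissue the
  flat level $b = m\sqrt{(1-s^2)/(s^2(T-1))}$ obtained by inverting the SPM
  formula (`spm_flat_background()`); planted SPMs span 0.92–1.0 and planted
  abundances 10–1000 FPKM;
* **background genes** with a log2-normal baseline (mean 3, SD 2) and
  per-tissue fold offsets truncated at ±1.6 log2 units. The truncation is
  structural, not cosmetic: a bounded fold range guarantees every
  background gene's SPM stays below 0.9, so the "background" truth class
  can never accidentally satisfy the selective rule and planted-recovery
  precision is a meaningful quantity. Genes with stronger single-tissue
  dominance are, by definition, selective and belong to the planted class;
* **replicate noise**: log-normal, SD 0.25 log2 units by default (typical
  of well-behaved RNA-seq replicates); zero noise makes every replicate
  equal its tissue mean, giving exact planted recovery;
* **lncRNAs in all four overlap classes** (clean intergenic,
  sense-exonic-overlap, embedded in a retained intron, embedded in a
  non-retained intron), each hosted/anchored by a coding gene and each
  validated at generation time against the package's own filter
  predicates — a mislabelled plant aborts the simulation;
* **peak tracks for a 7-tissue panel**: H3K4me3 at every coding promoter;
  true enhancers > 3 kb from every TSS and H3K4me3 peak and pairwise
  separated beyond the merge gap; shared enhancers at identical
  coordinates in all tissues; generic tissue-unique enhancers; flanking
  target-unique enhancers 10–30 kb from 53% of the planted selective
  genes; promoter-proximal H3K27ac decoys that the distance rule must
  remove; promoter TF peaks for 74.4% of the planted selective genes; all
  intensities Gamma(2, scale 20);
* **co-expressed pairs** drawn from a bivariate normal on the log2 scale
  at a configurable latent correlation (0.8 by default, mirroring a
  regulator/lncRNA co-expression pattern), with offsets bounded like the
  background so the pair can never be mistaken for a planted selective
  gene.

Genes are laid on one long pseudo-chromosome at 2.4 Mb spacing, and the
generic/shared enhancer background is placed mid-gap, more than 1 Mb from
both flanking TSSs. This isolates every gene's capped regulatory domain,
so the enhancer–gene association truth is exactly the deliberately planted
flanking set. That is a deliberate departure from real genomes, where
domains of neighboring genes share intergenic space and an enhancer often
associates with two genes; the association *rule* is still exercised on
dense, overlapping-domain instances in the unit tests.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: read-level effects (mapping,
length/GC bias), batch effects and cross-tissue correlation structure in
the background, transcript-level quantification and the transcript→gene
collapse, peak-calling noise (planted peaks have exact boundaries), and
biologically clustered gene neighborhoods. Recovery rates on synthetic
data are upper bounds under the stated noise model, not estimates of
performance on any particular compendium.

## Numerical choices

* SPM uses a single vectorized norm; rows with zero norm are flagged, never
  divided. Agreement with the brute-force cosine oracle is required to
  1e-12 and unit-norm deviation to 1e-10 in the tests.
* Ranked outputs break ties deterministically (descending SPM or
  correlation, then lexicographic gene id); the query gene is pinned to
  rank 1 in correlation rankings.
* The log2 pseudocount (0.1) keeps zero-FPKM tissues finite while staying
  below the abundance floor; correlations are therefore *not* exactly
  invariant to rescaling one gene's FPKM unless the pseudocount is 0 (the
  invariance tests set it so).
* Intron retention is consumed as a precomputed boolean table; the bundled
  helper derives it from per-base coverage as median intron coverage at or
  above 25% of the flanking-exon median — a conventional operational
  definition, kept isolated and overridable because retention calling is
  genuinely method-dependent.
* All generators draw from an explicitly seeded RNG and restore the
  caller's RNG state; a fixed seed reproduces every output file byte for
  byte, and the pipeline writes no timestamps or locale-dependent content.

## Problem sizes in the tests

The recovery checks run at 50 planted selective genes over 5,000
background genes, 22 tissues × 3 replicates (one zero-noise run plus 20
noisy seeds); the SPM oracle comparison uses 1,000 random 50 × 22
profiles; merge/uniqueness checks use 200-interval random sets and the
7-tissue planted panel; correlation recovery uses 1,000 seeds for the
Fisher-z coverage of latent $r = 0.8$ at $n = 22$ and 50 seeds for the
planted-partner ranking among 500 background genes. These sizes make the
Monte-Carlo rates stable at the asserted bounds while keeping the full
suite fast.

## Limitations

* The pipeline consumes FPKM tables and peak calls; it does not quantify
  expression or call peaks, and inherits whatever biases those upstream
  steps introduce.
* SPM treats biologically similar tissues as independent axes: a gene
  shared by two sister tissues is penalized relative to a truly unique
  one (its SPM tops out at $1/\sqrt{2} \approx 0.707$ — exactly the lower
  edge of the preferential band).
* The selective/preferential thresholds are conventional but arbitrary;
  results near the boundaries are sensitive to them, which is why every
  threshold is a visible, validated parameter.
* Tissue-uniqueness of enhancers is any-overlap against the compared
  tissues only; adding tissues can only shrink the unique set.
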