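---
title: "Quantifying the supragenic organization of glycoside hydrolase genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the supragenic organization of glycoside hydrolase genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghsynteny)
```

## The question and the model

Complete carbohydrate deconstruction needs several glycoside hydrolases
(GHs) acting together, often with sugar transporters; genes supporting one
process tend to be co-expressed when physically close, so the arrangement of
GH genes along a bacterial replicon — scattered or clustered, codirectional
or not, near transporters or not — is itself a phenotype. This package
measures that arrangement and asks, for each genome, whether it could have
arisen by chance given the genome's size and GH-gene content.

The coordinate system is deliberately coarse. A gene's position is its
ordinal rank among the protein-coding features of its replicon (the "PEG
number"), and distance between genes is the difference of ranks. This throws
away nucleotide distances and intergenic structure but is robust to
annotation differences and makes the null model exact: randomizing a genome
is just re-sampling ranks. Ranks are always recomputed 1..n per replicon, so
gapped accession numbering in source databases cannot create phantom
distances.

For a gene of a class, the synteny score (SSc) is the shortest rank distance,
upstream or downstream, to the next gene of the same class on the same
replicon; SSc = 1 means contiguous. A gene that is its replicon's only class
member has no defined SSc and is treated as unclustered everywhere. Distances
never cross replicons: a plasmid is scored on its own.

## Null model and its closed form

The randomized counterpart of a genome keeps each replicon's size, topology
and class-gene count and re-places the genes uniformly without replacement.
Summaries over replicates (default 5,000, matching the resolution at which
the 2.5% and 97.5% quantiles are stable) give the null band for any synteny
statistic, and an add-one empirical p-value
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$ avoids reporting zero.

The expected number of genes at SSc = 1 has an exact closed form used as an
independent check on the simulator. Condition on one placed gene: the other
$g-1$ genes occupy a uniform $(g-1)$-subset of the remaining $n-1$ slots, so
on a circular replicon the probability that both flanking slots are free of
class genes is $\binom{n-3}{g-1}/\binom{n-1}{g-1}$ and

$$E[\#\{SSc = 1\}] \;=\; g\left(1 - \frac{\binom{n-3}{g-1}}{\binom{n-1}{g-1}}\right).$$

On a linear replicon the two end positions have a single flanking slot and
are weighted $2/n$. For $n = 5{,}000$, $g = 300$ the circular form gives
34.82: roughly 35 contiguous GH genes are expected by chance in a genome of
that size and GH content, which is why an observed cluster count alone never
demonstrates selection. The test suite holds the simulator to this formula
within four standard errors, and to exhaustive enumeration over all
placements on replicons of up to 8 PEGs.

### Normality across simulation regimes

Whether a null statistic is usably Gaussian depends on the GH-gene
frequency. We summarize normality with the Shapiro–Wilk test, applied to at
most 5,000 values (the test's implementation limit; larger samples are
seeded subsamples). Two statistics behave differently, and we track both:

* the per-replicate **mean SSc** is an average over all placed genes and is
  close to normal even in sparse genomes — at 5,000 replicates its W stays
  above 0.99 everywhere we simulate, while its p-value still detects the
  residual skew in the sparse (&lt; 1% GH) regime (p far below 0.01) and not
  in the dense regime (p &gt; 0.01 at 6%);
* the per-replicate **count of genes at SSc = 1** is strongly discrete when
  its expectation is small, so its W collapses (0.13–0.62 across our sparse
  conditions) and recovers to &ge; 0.98 only in the dense regime.

The regime boundary is therefore asserted in the tests on the p-value for
the mean and on W for the count; quoting W for a near-degenerate mean would
claim a contrast the statistic cannot express at this sample size.

## Orientation and its null

The unit of the codirectionality analysis is the sequential pair of class
genes, whose gap is exactly the pair's SSc; restricting to "clustered pairs"
filters pairs by gap, not genes by score. Under no selection each pair is a
fair Bernoulli trial, and we use the exact two-sided binomial test with
equal-tail doubling (twice the smaller tail, capped at 1) rather than a
normal approximation, because most genomes contribute few pairs. On a
circular replicon with $k \ge 2$ members the wrap pair is included, giving
$k$ pairs; whether real chromosomes should contribute that pair is not
observable from annotation alone, so the per-replicon topology flag controls
it (see below).

## GH:transporter colocalization

A GH gene is colocalized with a transporter class when a gene of that class
lies within 10 PEGs (the cluster threshold is 5; the looser association
threshold reflects that transporters sit near, not within, enzyme runs). The
per-class nearest gene is recorded; ties between an upstream and a
downstream candidate at the same distance go to the upstream gene, a purely
reporting-level convention. A gene carrying both a GH and a transporter
domain is a GH gene for synteny purposes and is excluded as its own partner.
The denominator of the colocalized fraction is the GH-gene count, so the
statistic is comparable across genomes with different transporter
repertoires.

Transporter classes come from a Pfam accession map. The SUS class is the
TonB-dependent transporter core (barrel PF00593, plug PF07715, with the
optional extensions PF13715/PF07660); a SusD partner is not required, since
requiring it would silently empty the class in genomes annotated without
lipoprotein calls. The shipped MFS/ABC/PTS lists are the canonical Pfam
families for each class and are explicitly provisional — the map file is the
single source of truth and is meant to be curated per study.

## Cohort statistics

Across a cohort, `correlation_and_slope()` gives the Pearson r and OLS slope
of GH count on PEG count, and `variance_partition()` decomposes the variance
of the clustered-gene count with sequential (type-I) sums of squares in the
fixed order genome size, GH count, interaction — the only decomposition in
which four parts labelled "% variance explained" plus a residual sum to
100%. The response is the *count* of clustered genes by default (the
frequency is available by passing the corresponding column): counts keep the
regression on the same scale as the predictors and avoid ratio-vs-ratio
artifacts; a constant response returns a flagged zero correlation instead of
failing a whole cohort run.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| cluster threshold | 5 PEGs | SSc at or below which a GH gene is clustered; separates closely linked but non-contiguous genes from scattered ones |
| colocalization threshold | 10 PEGs | maximum GH–transporter distance for a GH:TR cluster |
| `s_max` | 20 | largest SSc tabulated in N_SSc/F_SSc |
| `min_score` | 25 bits | domain-hit bit-score floor; the profile search's own gathering thresholds are not recoverable from hit tables, and 25 bits is a conservative Pfam-style floor |
| null `iterations` | 5,000 | replicates per null distribution |
| topology | circular | per-replicon flag; wrap-around distances on circular replicons |

Topology deserves a note: complete bacterial chromosomes are almost always
circular, so circular (with wrap-around SSc, wrap-chaining clusters and the
wrap pair) is the default, and linear is a per-replicon opt-out for
linear chromosomes and unresolved contigs. Both behaviors are first-class
and tested.

## The synthetic generator

`generate_genome()` emulates the regimes the null models cover: one replicon
of 1,000–15,000 PEGs carrying 0.5–10% GH genes (defaults 5,000 and 300),
placed uniformly (`cluster_count = 0`, the null regime and the default) or
as planted clusters with within-cluster gaps from `gap_choices` (default
1–5, so planted clusters are clustered at the default threshold),
within-cluster strand persistence `codir_prob` (default 0.9, the level seen
in strongly clustered lineages), and transporters optionally co-placed
within 10 PEGs of GH genes. Cluster layouts are rejection-sampled with a cap
of 1,000 attempts, after which the spec is reported infeasible.

What it does **not** emulate: real genomes have operon scaffolds, rRNA/tRNA
islands, replication-strand bias, multi-replicon architecture with biased
plasmid content, and GH families with correlated placement. Passing tests on
synthetic cohorts therefore demonstrates that the statistics measure what
they claim on genomes whose generating process is known — not that any
particular biological lineage is clustered. Conclusions about real genomes
must come from running the pipeline on real annotations.

## Numerical conventions and degenerate inputs

* Percentages in printed reports are truncated (not rounded) to one decimal
  — a genome is never reported more GH-rich or more clustered than it is;
  full-precision values stay in the summary objects and cohort tables.
* Undefined SSc (single class member) is `NA` in tables, counts as
  unclustered in fractions, and is excluded from mean SSc.
* A genome with no GH genes summarizes with zero counts and `NA` fractions;
  fraction functions that would divide by zero raise errors naming the
  condition.
* Cluster members are stored in chain order along the replicon (for a
  wrap-spanning cluster this starts after the largest gap), which equals
  ordinal order for every non-wrapping cluster.
* All simulations take explicit seeds; cohort generation derives one stream
  per genome from the master seed, keeping derived seeds inside 32-bit
  integer range.

## Problem sizes used in the test suite

The suite exercises exhaustive enumeration up to 8-PEG replicons, Monte
Carlo checks at 2,000 replicates on genomes up to 1,000 PEGs, the
5,000-replicate calibration conditions (5,000 PEGs, 300 GH genes), and
200-replicate uniformity checks of the empirical p at 2,000 PEGs — sizes
chosen so the whole suite stays in the tens of seconds while every claim is
still backed by a sampling-error bound (four standard errors throughout).

## Known limitations

* PEG-rank distance ignores base-pair spacing; two "contiguous" genes may be
  separated by a long intergenic region.
* Operon prediction is out of scope: codirectional clusters are a necessary,
  not sufficient, condition for operons.
* The variance partition is an ordinary fixed-order linear decomposition; it
  is not phylogenetically corrected, and lineage pseudo-replication is the
  user's responsibility (group summaries help, mixed models are out of
  scope).
* Domain-level identification is consumed, not performed: garbage hit tables
  yield garbage classes, bounded only by the bit-score floor.
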