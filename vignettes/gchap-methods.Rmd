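---
title: "Gene-CDS-haplotype diversity analysis: models and methods"
author: "gchapr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-CDS-haplotype diversity analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gchapr)
```

## The object of study

A gene-CDS-haplotype (gcHap) is the vector of SNP alleles an accession
carries at the coding-sequence positions of one gene. Two accessions share
a gcHap exactly when their CDS allele vectors are identical — no
clustering, no one-mismatch merging. This definition makes the haplotype a
proxy for the encoded protein variant and gives every downstream statistic
a discrete, countable unit. Cultivated rice is predominantly selfing, so
genotypes are overwhelmingly homozygous and an accession's CDS genotype
reads directly as a haploid allele vector.

The pipeline works on four inputs: SNP genotypes (VCF 4.x), gene models
(GFF3 CDS features), an accession panel labelled by population
(`Xian`, `Geng`, `Aus`, `Bas`, `Admix`) and variety class (`LAN` landrace,
`MV` modern variety, `other`), and optionally a phenotype table over the
15 standard agronomic traits (`gchap_traits()` lists them with units).

## Haplotype calling and its policy choices

Only SNPs define gcHaps; indel and MNP records are skipped (and counted)
at read time. Coordinates are kept 1-based inclusive end to end — the
native convention of both VCF and GFF3 — so no interval arithmetic ever
crosses a convention boundary. A SNP belongs to a gene when its position
lies inside any CDS interval, boundaries included, regardless of strand.

Missing and heterozygous calls need a policy, and the data sources for
panels of this kind do not document one. The default, `exclude`, drops an
accession from a gene if it carries *any* missing or heterozygous call at
the gene's CDS sites: the strictest reproducible rule, and the right
default for inbred material where residual heterozygosity is rare. The
alternative `ref_fill` policy replaces such calls with the reference
allele and keeps everybody; it exists so the sensitivity of downstream
results to the policy can be measured rather than assumed. All frequency
denominators are **non-excluded** accessions (per subset where
applicable), so counts always sum to the analyzed sample.

Haplotypes are ranked by descending global count, ties broken by first
occurrence in accession order (deterministic for a fixed input), and named
`Hap1, Hap2, ...`. Naming is global — `Hap1` denotes the same allele
vector in every population table — which is what makes cross-population
comparisons and network node identities coherent. A *major* gcHap has
panel frequency >= 1% (boundary included; the comparison is done on counts
to keep it exact). A gene with zero CDS SNPs degenerates to a single
haplotype holding all accessions.

## Diversity statistics

**Shannon equitability.**
$E_H = \frac{-\sum_i p_i \ln p_i}{\ln S}$ over the $S$ haplotypes with
positive frequency, natural log (the base cancels only if numerator and
denominator share it; ln is the population-genetics convention). $E_H$ is
defined as 0 for a monomorphic spectrum — the $0/0$ case — which matches
how near-monomorphic genes are treated in published tables. $E_H$ depends
only on the frequency multiset: it is invariant to relabeling,
zero-frequency padding, and replication of the panel.

**Nei's identity.**
$I = \frac{\sum_i x_i y_i}{\sqrt{\sum_i x_i^2 \sum_i y_i^2}}$ over the
union of the two populations' haplotype sets (absent haplotypes enter as
zero). High identity means similar composition; low identity means strong
differentiation. Symmetric, in $[0, 1]$, equal to 1 iff the frequency
vectors coincide.

**Fixation index.** The published analyses name only "F-statistic", so an
estimator had to be chosen; `gchapr` uses Nei's $G_{ST}$ on haplotype
frequencies with sample-size weights $w_k = n_k / \sum n$:
$H_S = \sum_k w_k (1 - \sum_i p_{ki}^2)$,
$H_T = 1 - \sum_i \bar p_i^2$,
$F_{ST} = (H_T - H_S) / H_T$ (0 when $H_T = 0$). The estimator name is
written into the output table (`estimator` column) so results are
self-describing. Weir–Cockerham or AMOVA-style estimators would give
slightly different values; only the $G_{ST}$ properties (bounds, zero for
identical populations, one for fixed disjoint populations, monotone under
divergence) are asserted by the test suite.

## The landrace/modern shift and its significance test

For a population group with both classes, each gene gets $E_H$ and the
haplotype count on the LAN and MV subsets, their differences, and a
significance test. The published tables mark rows with `*`/`**` without
naming a test, so the package supplies a defensible one: a **label
permutation test** on $|\Delta E_H|$, reshuffling LAN/MV labels among the
group's non-excluded accessions with subset sizes fixed,
$p = (1 + \#\{ \text{perm} \ge \text{obs} \}) / (1 + \text{reps})$.
A permutation test is preferred over a bootstrap because the null
hypothesis — no landrace/modern structuring — corresponds exactly to label
exchangeability. Defaults: 10,000 replicates, seed 1. Internally the
accession rows are put in a canonical order before permuting, so the
p-value depends only on the (haplotype, class) composition, the seed and
the replicate count, never on input row order. Note the attainable
minimum $p$ is $1/(\text{reps}+1)$; the `**` code ($p < 10^{-4}$)
therefore requires at least 10,000 replicates.

The *artificial selection* label is `up` exactly when the shift is
significant at 0.05. This follows the published tables' own usage, where a
row with a *negative* equitability change still carries `*` and `up`: the
label means "significant artificial-selection effect", not "diversity went
up". The sign information is in `delta_EH` itself.

Major-haplotype frequency drift between the classes is tested with a 2×2
chi-square (haplotype vs all others × LAN vs MV) without continuity
correction; results with any expected cell below 1 are flagged
`low_count` rather than suppressed.

Mean rows are reported at full precision (the TSV writer adds rounded
display columns alongside, mirroring the mixed precision of published
tables, which print e.g. −36.81818182 next to 3-decimal entries).

## Trait association

One-way ANOVA of each trait over the gene's major haplotypes — one factor,
haplotype — followed by Tukey HSD on all retained pairs (studentized-range
distribution) and a compact letter display computed by the insert-absorb
algorithm, implemented in `cld_insert_absorb()`: two haplotypes share a
letter iff their Tukey-adjusted $p \ge 0.05$. Groups need at least
`min_n = 10` phenotyped accessions (no published minimum exists; 10 keeps
group means stable without discarding real minor haplotypes — the value is
recorded in the result object). Genes with fewer than two eligible groups
are flagged not-analyzable, matching the exclusion of single-gcHap genes
from published association counts.

Associations with ANOVA $p < 10^{-7}$ carry a `strong` flag. This is a
fixed threshold, not FDR control, because that is how such scans are
reported in this literature; the raw p-value is always emitted alongside
so any correction can be applied downstream.

The favorable/unfavorable comparison takes the highest- and
lowest-frequency major haplotype of each gene (ties broken by rank) and
compares every trait with **Welch's** unequal-variance t-test — the two
groups are wildly unbalanced by construction, so pooling variances would
be wrong. Comparisons with fewer than two phenotyped accessions in either
group are skipped with a recorded reason.

One documented discrepancy: the figure captions of the source analyses
mention a two-way ANOVA while the methods text specifies one-way with
Tukey. With a single factor available (haplotype), one-way is the
implementable reading and is what the package does.

## Haplotype networks

Distances between haplotypes are Hamming distances on allele vectors —
the minimum number of single-site mutations. The network is built
Kruskal-style over candidate edges sorted by (steps ascending, haplotype
rank pair): an edge joining two components becomes a spanning edge
(`in_msn = TRUE`); an edge inside one component is kept as an
*alternative link* when its steps equal the bottleneck weight on the
spanning path between its endpoints — i.e., the step value at which its
endpoints' components merged — so equally parsimonious reticulations
survive, as in standard haplotype-network renderings. A probabilistic
(95% parsimony) connection limit is deliberately **not** computed; the
limit is a plain user parameter in mutation steps, default unlimited,
which keeps the construction deterministic and testable. Median
(unsampled intermediate) haplotypes are never inserted, and layout
aesthetics are left to `autoplot()`.

## The synthetic-data generator

`sim_config()` + `simulate_panel()` produce a complete fixture: VCF,
GFF3 (gene → mRNA → CDS chains, two CDS exons per gene), panel TSV,
trait TSV, and a JSON manifest with the ground truth. The generator
emulates the features that matter to the pipeline:

* **Haplotypes on a mutation tree.** Root all-reference; each new
  haplotype copies a parent and mutates one previously unmutated site.
  Every site mutates once, so vectors are unique and Hamming distance
  equals tree-path length — an exact ground truth for network recovery.
  Consequently at most `sites_per_gene + 1` haplotypes are feasible.
* **Population structure.** Per population, landrace frequencies are
  Dirichlet(α); α = 0.5 by default, giving the skewed,
  dominant-`Hap1` spectra seen in real panels.
* **Breeding drift.** MV frequencies are
  $(1-d)\,p_{LAN} + d\,e_{\arg\max p_{LAN}}$: mass moves to the dominant
  haplotype, so rare haplotypes drop out of the modern sample and the
  modern haplotype count falls — the direction real landrace/modern
  comparisons show. Default $d = 0.3$, a visible but not degenerate shift.
* **Panel composition.** Defaults mirror the 3,010-accession panel's
  landrace/modern split: 732/358 Xian, 328/139 Geng.
* **Traits.** Baseline (field-plausible per-trait values) + additive
  per-haplotype effects + Normal(0, `trait_sd`) noise.
* **Call noise.** Heterozygous and missing calls injected per genotype
  at configured rates (both 0 by default, so recovery is exact).

Each gene draws from an RNG stream derived from the master seed, so
per-gene output is stable when the gene count changes.

What the generator does **not** emulate: coalescent genealogies,
recombination within genes, linkage to non-CDS variation, genotyping
error structure, or trait correlations. Passing tests on synthetic data
therefore demonstrate correctness of the algorithms under the stated
model, not robustness to every feature of real panels.

## Numerical choices and degenerate inputs

* Major-haplotype thresholding compares counts
  (`count >= threshold * n - 1e-9`), keeping the >= 1% boundary exact.
* $E_H := 0$ when $S = 1$; empty spectra ($n = 0$) are errors, not zeros.
* ANOVA with numerically zero between-group variance returns $F = 0$,
  $p = 1$; zero within-group variance with distinct means returns
  $F = \infty$, $p = 0$, with Tukey p-values falling back to 0/1 by mean
  equality.
* Permutation-test ties are counted as exceedances (with a $10^{-12}$
  guard), the conservative direction.
* Haplotype-count ties everywhere resolve by first occurrence, making
  every output deterministic for a fixed input order.

## Problem sizes used by the checks

The test suite and the acceptance script run at desk scale by design:
500 null datasets × 999 permutations for the type-I calibration of the
permutation test (expected rejection 0.05 ± binomial noise), 100 seeds at
n = 200 per group for the planted-effect power check ($p < 10^{-7}$
expected in ≥ 95%), ≤ 8-node instances for exhaustive spanning-tree
enumeration, and 3-gene zero-noise panels at the default composition for
end-to-end identifiability. Published full-panel quantities that require
the complete 3,010-accession genotype resource (per-gene haplotype
counts in the hundreds, panel-wide association counts) are out of reach
of synthetic reproduction and are represented instead by the bundled
per-gene summary rows, whose aggregate statistics the package recomputes
exactly.

## Known limitations

* No phasing and no imputation: heterozygous calls are policy, not data.
* No protein-level consequence annotation (synonymous and missense
  changes are equally "mutations").
* No kinship or population-structure correction in the trait ANOVA — by
  design, to match the analysis being reproduced; treat strong
  associations as descriptive, not causal.
* The Fst estimator choice is a convention; values are comparable within
  this package, not across estimators.
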