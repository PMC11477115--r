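---
title: "Codon usage bias analysis with cubtools: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias analysis with cubtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubtools)
```

# The problem

Synonymous codons are not used uniformly. In chloroplast coding sequences
the imbalance is shaped by two forces that the field's standard diagnostics
try to separate: **mutation pressure**, which acts mostly on the free third
codon position and drags synonymous usage toward the genome's equilibrium
base composition, and **natural selection** (typically translational), which
enriches a specific preferred codon in each family, most strongly in highly
expressed genes. `cubtools` implements the complete workbench used in
comparative chloroplast studies of this question: CDS quality filtering,
composition and skew statistics, the codon-usage index suite, high-frequency
and optimal codon classification, the mutation-vs-selection diagnostics, a
heterologous-host comparison, and RSCU-based clustering of species — plus a
seeded generator of synthetic CDS sets with known ground truth so that every
stage is testable without external data.

# Filtering model

A candidate CDS is retained only if it starts with ATG, ends with
TAA/TAG/TGA, has no internal in-frame stop, has length divisible by three
and at least `min_len` (default 300 nt), and contains only A/C/G/T. Choices
behind the less obvious rules:

* **Genetic code.** The plastid (bacterial) translation table, whose
  codon-to-amino-acid map coincides with the standard code over all 64
  codons.
* **Ambiguity codes** (N, R, ...) reject the whole gene rather than being
  partially counted; a partially counted gene would bias every downstream
  within-family fraction.
* **Alternative start codons** (GTG, TTG) are rejected: the filter demands
  ATG literally, as chloroplast CUB studies conventionally do.
* **Duplicate gene names** (e.g. inverted-repeat copies of the same gene)
  are collapsed to the first occurrence. Counting a gene twice would double
  its weight in every pooled statistic. The behaviour is a flag
  (`dedupe = TRUE` by default) because annotations differ in whether IR
  copies and trans-spliced genes appear once or twice.
* GenBank locations are treated as 1-based inclusive; join() features are
  spliced and minus-strand features reverse-complemented to 5'→3'.

Filtering is idempotent, and every retained gene translates to a protein
with a terminal stop and no internal stop — both are enforced by tests.

# The index suite

All indices operate on in-frame codon counts over a fixed 64-codon domain;
RSCU-family statistics use the 59 *informative* codons (all but ATG, TGG
and the stops).

* **RSCU** — count divided by the family mean; 1 = no bias. **RFSC** —
  count divided by the family total; `RSCU = n_i * RFSC`. Families with
  zero occurrences are *undefined* (`NA`), never 0, and undefined values
  are excluded pairwise downstream.
* **ENC** (effective number of codons) — Wright's estimator: per amino
  acid observed `n >= 2` times, homozygosity
  `F = (n * sum(p^2) - 1)/(n - 1)`; class means over degeneracies
  {2, 3, 4, 6}; `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, capped at 61. If
  the 3-fold class (Ile) is unobserved it is imputed as `(F2 + F4)/2`; a
  missing 2-, 4- or 6-fold class (or a zero class mean) leaves ENC
  undefined. This mirrors the behaviour of the classic CodonW
  implementation.
* **Expected ENC** under pure mutation pressure:
  `ENC = 2 + s + 29/(s^2 + (1 - s)^2)` at GC3s `s` — the reference curve of
  the ENC-plot. The signed **ENC ratio** is `(expected - observed)/expected`
  so that genes *below* the curve (more bias than mutation explains) have
  positive ratios; this sign convention makes the reported ratio ranges read
  naturally.
* **SCUO** — information-theoretic codon-usage order: per degenerate amino
  acid the normalized entropy deficit (base-2 logs), weighted by that amino
  acid's share of degenerate-codon occurrences; 0 = uniform usage,
  1 = one codon per family.
* **MILC** — a length- and composition-corrected log-likelihood distance
  between a gene's within-family usage and a reference usage:
  `sum_a M_a / L - C` with `M_a = 2 sum_c O_c ln(f_c/g_c)` and
  `C = sum_a (r_a - 1)/L`. The reference defaults to the species' pooled
  filtered CDSs (genome-wide usage); `L` is the gene's scored
  (informative-codon) count. A reference zero for an observed codon gets a
  0.5 pseudocount spread over that family. The per-species summary is the
  gene mean.
* **CAI** — geometric mean of `w = RSCU/max RSCU` weights. Because no
  external high-expression reference exists for these genomes, the
  reference set is the analysis' own lowest-ENC decile (the putative
  high-expression genes); unobserved reference codons are floored at 0.01.
* **Fop / CBI** — fraction of optimal codons and Chargaff-style bias index
  over degenerate-family occurrences, with the optimal set taken from the
  ENC-decile contrast below.
* **Protein properties** — Kyte–Doolittle GRAVY, aromatic fraction (F/Y/W),
  and isoelectric point by bisection of the Henderson–Hasselbalch net
  charge with the EMBOSS pKa set (termini 8.6/3.6; C 8.5, D 3.9, E 4.1,
  H 6.5, K 10.8, R 12.5, Y 10.1) to |charge| < 1e-4 on [0, 14].

# Codon classification

* **High-frequency codons**: RFSC > 0.60, or RFSC > 1.5 times the family
  mean. The family mean of RFSC is read as `1/n_i` — the only
  parameter-free interpretation of "50% higher than the mean frequency of
  its synonymous counterparts".
* **Expression deciles**: genes sorted by ENC; the lowest decile is the
  putative high-expression set, the highest the low-expression set. The
  decile size is `ceiling(fraction * n)` — with 37–41 genes per chloroplast
  the rounding rule is visible, so it is documented and tested — and ENC
  ties break lexicographically by gene id for determinism.
* **Optimal codons**: RSCU computed on the *pooled counts* of each decile
  set (not per-gene averages); a codon is optimal iff RSCU_high > 1,
  RSCU_low < 1 and the difference exceeds 0.08.

# Mutation-vs-selection diagnostics

* **Neutrality plot**: OLS of GC12 on GC3 with Pearson r. Slope near 1 —
  mutation dominates; near 0 — selection constrains positions 1–2
  independently of the third.
* **ENC-plot**: observed ENC against GC3s with the expected curve; the
  ENC-ratio histogram uses 0.05-wide bins aligned to multiples of 0.05
  (left-closed, right-open), and the reported band is the fraction of genes
  with ratio in [-0.05, 0.10].
* **PR2-plot**: per gene, x = G3/(G3+C3), y = A3/(A3+T3); (0.5, 0.5) is the
  parity expectation under strand-symmetric mutation alone.
* **Correspondence analysis** is run per species on the gene x 59 RSCU
  matrix (undefined entries as 0, all-zero columns dropped): standardized
  residuals of the correspondence matrix decomposed by SVD; principal
  coordinates and inertia percentages follow the textbook definitions, and
  the implementation is tested to 1e-8 against an independent
  eigendecomposition and against `vegan::cca`. Using RSCU (rather than raw
  counts) keeps amino-acid composition out of the ordination.
* **Correlation suites** default to Spearman rank correlation (the CodonW
  convention; the studies this package follows do not name their test), with
  Pearson available via `cor_method`. Missing values are excluded pairwise;
  raw p-values are reported without multiplicity correction, matching field
  practice for these descriptive tables.

# Host comparison and clustering

Host comparison uses per-thousand frequencies over all 64 codons — the
percentages conventionally reported (e.g. 12/64 = 18.75%) imply the 64-codon
denominator — and flags a codon as divergent when species/host <= 0.5 or
>= 2 (boundaries count as divergent: "exceeding 0.5 yet below 2" is the
negligible zone). The orientation is fixed as species/host and the measure
is deliberately asymmetric. The four packaged host tables are **synthetic
stand-ins** generated from a parametric model (typical amino-acid
composition, host-typical GC3, a preferred-codon boost); they exercise the
machinery and demonstrate the workflow but are not snapshots of the public
codon-usage database — users with network access should supply real tables
via `read_host_table()`.

Species clustering uses squared Euclidean distances between pooled
59-codon RSCU vectors and between-groups average linkage (the method the
term "intergroup linkage" denotes in SPSS, where it is the default).
Species are sorted lexicographically before clustering, which together with
`stats::hclust` makes the topology invariant to input order; trees
serialize to newick via `ape`.

# The synthetic-data generator

The generator emulates the statistical structure the diagnostics assume:

* **Mutation** acts on the third position only: within each family the
  G/C-ending codons jointly receive probability equal to the gene's GC3
  target `t` (split evenly within the G/C-ending and A/T-ending subsets, so
  `P(G/C-ending) = t` holds exactly in every family, including the
  asymmetric 3-fold Ile family). Met and Trp are emitted as-is, and the
  stop is drawn uniformly from the three stops.
* **Selection** multiplies a planted preferred codon's weight by `exp(s)`.
* Amino acids are i.i.d. from a configurable profile (default uniform);
  genes are independent (no tree-structured evolution of homologs).
* One root seed drives per-gene substreams, so extending a set never
  perturbs earlier genes and equal seeds give byte-identical FASTA.

The target is stated as GC3s (synonymous third positions): GC3 over *all*
codons is mechanically inflated by the invariant G-ending Met/Trp codons
(about +0.07 at target 0.2 under a uniform amino-acid profile), so GC3s is
the quantity the generator can and does control without bias.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: amino-acid composition differences between genes,
length/expression correlations, context-dependent mutation, strand
asymmetry, and phylogenetic correlation between species. Recovery results
on the battery demonstrate the *estimators* are correct under their own
assumptions, not that real chloroplast data satisfy those assumptions.

## The fixed regime battery

Calibration and acceptance checks run on a deterministic grid
(`regime_battery()`): mutation-only sets at GC3s targets
0.2/0.35/0.5/0.65/0.8; selection sets (GC3s 0.5) at s = 0/0.5/1/2/5; two
clustering regimes (GC3s 0.30 vs 0.60, three replicate species each); and a
"recovery" set for planted optimal-codon detection. Sizes are 40 genes of
300–600 codons per set — the gene count matches the chloroplast scale
(37–41 filtered CDSs per genome), and the length floor of 300 codons keeps
the per-gene variance of Wright's ENC estimator small enough that genes sit
close to the expected curve under pure mutation.

The recovery set deserves its design note. Planted preferred codons are
G/C-ending; the background is AT-rich at GC3s = 0.25; half the genes carry
s = 4, half s = 0. Two facts force the 0.25 choice (a value inside the
GC3 range actually observed in chloroplast CDS sets). First, the planted
Ile codon ATC has mutational-null RSCU of `3t`; any background with
t >= 1/3 makes its "low-expression RSCU < 1" condition unsatisfiable by
construction. Second, selecting the *highest-ENC* genes as the
low-expression pool enriches for within-family evenness (ENC noise and
evenness are the same thing at the gene level), which inflates
minority-codon RSCU toward 1; the planted codons must therefore be genuine
mutational minorities with a margin. With t = 0.25 every planted codon has
null RSCU <= 0.75 and the decile procedure recovers >= 80% of the planted
set (typically 94–100%).

# Numerical choices and degenerate inputs

* Undefined statistics (empty families, zero denominators, sub-minimal
  gene sets) propagate as `NA` and are excluded pairwise; they are never
  silently zeroed, with two deliberate exceptions where a container
  requires completeness: RSCU matrices entering CA and clustering impute
  `NA` as 0 (logged).
* ENC is capped at 61; SCUO uses `0 log 0 = 0`; CAI floors unobserved
  reference codons at 0.01; MILC uses a 0.5 family pseudocount for
  reference zeros.
* CA drops singular values below 1e-12; pI bisection stops at
  |net charge| < 1e-4.
* Ties: ENC-decile membership breaks by gene id; clustering input is
  label-sorted; histogram bins are left-closed.
* Fewer than 2 filtered genes abort an analysis; fewer than 10 genes with
  defined ENC disable the decile-based statistics (CAI, optimal codons)
  with a warning rather than failing the whole analysis.

# Problem sizes used by the checks

The shipped test-and-calibration suite works at deliberately desk-sized
scales chosen as the smallest sizes at which each law-of-large-numbers
property is comfortably stable: 17 battery sets x 40 genes x 300–600
codons; a 200-gene set for the neutrality-slope null; 1000 replicates of
n = 40 for the Spearman type-I calibration; brute-force oracles on
matrices up to 5 x 5 and trees up to 5 leaves.

# Known limitations

* The GenBank reader is a minimal flat-file CDS extractor (LOCUS/FEATURES/
  ORIGIN, join/complement); it does not resolve trans-spliced genes
  scattered across features (each CDS feature is one gene) or external
  sequence references.
* CAI without an external reference set measures adaptation to the
  genome's own low-ENC decile; comparisons across species with different
  decile compositions should be read accordingly.
* The host tables are synthetic stand-ins (above).
* No multiple-testing correction is applied to correlation tables by
  design; treat the p-values descriptively.

# A short run

```{r example}
sim <- simulate_cds_set(n_genes = 40, length_codons = c(300, 600),
                        gc3_target = 0.3, regime = "mutation_only",
                        seed = 7, species = "demo")
fit <- cub_analysis(sim$set)
fit
head(fit$optimal)
```

Cross-species comparison and clustering:

```{r compare}
b <- regime_battery(seed = 7, n_genes = 15, length_codons = c(300, 400))
fits <- lapply(b[c("clustA_1", "clustA_2", "clustB_1", "clustB_2")],
               function(x) cub_analysis(x$set))
cmp <- cub_compare(fits)
cmp$cluster$newick
```
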