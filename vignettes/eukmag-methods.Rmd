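---
title: "Methods: screening, trophic scoring and co-occurrence networks for eukaryotic MAGs"
author: "eukmag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, trophic scoring and co-occurrence networks for eukaryotic MAGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eukmag)
```

# Scope and philosophy

Recovering eukaryotic genomes from mixed-community shotgun metagenomes
leaves a long tail of downstream computation after the heavy lifting of
assembly, binning, gene prediction and annotation is done by dedicated
external tools. `eukmag` implements that tail as a small, fully tested
toolkit operating on plain files: bin screening and quality tiering,
ANI dereplication, reconciliation of gene-structure evidence, abundance
normalisation, a KEGG-Ortholog (KO) trophic-mode model with a composite
heterotrophy index, co-occurrence networks with community
connectedness, and phylogenetic diversity/gain. Upstream tools (binners,
EukRep-style domain classifiers, BUSCO/CheckM, kofamscan, CoverM, tree
builders) are consumed as tables, never executed.

Every stage is exercisable on synthetic fixtures generated by the
package itself, so the whole pipeline runs, deterministically, with no
external data.

# Bin screening and quality tiers

A candidate bin passes the eukaryotic screen when its total length
strictly exceeds 2.5 Mbp and the summed length of its
eukaryote-classified contigs strictly exceeds 90% of the total. The
2.5 Mbp default is anchored on the smallest known eukaryotic genome
(≈2.3 Mbp, a microsporidian); both comparisons are deliberately strict
so bins sitting exactly on a threshold fail it — thresholds are
measure-zero and a deterministic rule is worth more than the boundary
case. Contigs classified `unknown` count toward total length but not
eukaryotic length, i.e. they dilute the eukaryotic fraction; this is
the conservative reading of "content by length".

Eukaryotic bins tier by BUSCO completeness (>30% highly complete,
>10% reported, otherwise candidate). Prokaryotic bins tier by CheckM
estimates: high quality means completeness > 90% and contamination
< 5%; medium quality means completeness in [75, 90] with contamination
< 10% (a bin at exactly 90% falls to medium — the high tier's
inequality is strict).

## Dereplication

Genomes are clustered by single linkage (connected components) on
pairwise ANI at a 99% threshold. The representative of a cluster
maximises

$$S = \mathrm{completeness} - 5\,\mathrm{contamination} + 0.5\log_{10} N50,$$

a reduced form of the dRep default score: the strain-heterogeneity and
size terms are dropped because their inputs are out of scope here, and
the three coefficients are exposed as arguments. Ties break by total
length, then lexicographic id, so cluster structure and representatives
are invariant to input order.

## Taxonomic level and taxonomy-report descent

Percent identity of best hits maps to a taxonomic level via the bands
species (95, 100], genus (80, 95], family (65, 80], order (50, 65],
class (30, 50], none at or below 30. The printed bands share their
endpoints, so we fix the half-open convention lower-exclusive: a
boundary value belongs to the shallower level.

Cumulative-mapping taxonomy reports are descended from the root along
the maximum-percent child while that child's mapping strictly exceeds
8%, stopping at strain rank. "Deepest node still above 8%" is the
default reading; because the alternative "first node exceeding 8%"
is also defensible, it is available via `rule = "first"` (the first
non-root node on the same path).

# Gene-structure merging

Per locus, the ab initio exon set is the base prediction. When
protein-evidence exons exist, the agreement of the two tracks is
measured as the ratio of total exon counts, $\min(|ab|, |ev|) /
\max(|ab|, |ev|)$ — symmetric and dimensionless. At agreement ≥ 0.70,
interior ab initio exons without a corresponding evidence exon are
deleted (the first and last are always protected); evidence exons
without an ab initio correspondent are added. Correspondence is
same-strand overlap of at least 1 bp, the weakest defensible reading,
configurable via `min_overlap`. Whether evidence-only exons should be
added when the agreement test *fails* is genuinely ambiguous; the
default adds them (the addition clause reads as unconditional), and
`strict = TRUE` suppresses it. Overlapping post-merge exons are
coalesced by interval union, keeping evidence provenance since it is
alignment-backed. The merge is idempotent: merging a merged locus
against its own exons is the identity.

# Abundance

With $X$ reads recruited to MAG $i$ in sample $s$, $l_i$ the MAG length
in kb, and $N_s$ the sample's total trimmed reads in millions,

$$\mathrm{RPKM}_{i,s} = \frac{X_{i,s}}{l_i N_s}, \qquad
\mathrm{CPM}_{i,s} = \frac{\mathrm{RPKM}_{i,s}}
{\sum_j \mathrm{RPKM}_{j,s}} \times 10^6.$$

The $10^6$ scale factor follows the standard counts-per-million
construction. CPM columns sum to exactly one million, which makes
samples directly comparable, and CPM is invariant to rescaling $N_s$
(it cancels). Samples recruiting no reads yield an all-zero column with
a warning rather than an error: deep, poorly recruiting samples are
routine in environmental surveys and must not crash a pipeline.

# Trophic-mode model

## Feature selection

References with fewer than 500 present KOs are removed (exactly 500 is
kept — "fewer than" is read literally). Selection then uses
cross-validated permutation importance: the labelled references are
split into two stratified halves; a random forest grown on each half
scores permutation importance on the held-out half (implemented via
ranger's hold-out importance with zero case-weights); the two vectors
are averaged. Under this scheme unimportant features scatter
symmetrically around zero, so a null distribution is formed by
mirroring the non-positive importances, and each KO's empirical
p-value is its exceedance probability under that null (with add-one
smoothing so p is never exactly zero). KOs with p < 0.05 are selected —
0.05 being the conventional default for this mirrored-null test. A
constant feature has zero importance and is never selected; about 5% of
pure-noise features pass, as expected of an unadjusted empirical
p-value at that level.

## Classifier

A 500-tree classification forest is trained on a class-stratified 75/25
train/test split of the selected-KO matrix and reports held-out
accuracy. `tune = TRUE` runs a coarse out-of-bag grid over the number
of candidate features per split (½×, 1×, 2× the square-root default) in
place of a heavier tuning framework. All three labels — phototroph,
heterotroph, mixotroph — remain possible outputs; the model is not
collapsed to two classes even when mixotroph predictions are rare.

## Per-KO scores and the heterotrophy index

For each selected KO and mode, the occurrence ratio $a = K/n$ (number
of that mode's references containing the KO over the mode's reference
count) is transformed by

$$g(a) = \begin{cases} a & a > 0.5 \\ -(0.5 - a) & \text{otherwise,}
\end{cases}$$

scoring characteristic absence negatively without valuing absence over
presence ($g$ maps onto $[-0.5, 0] \cup (0.5, 1]$). An entity's mode
scores sum the per-KO scores over *all* selected KOs with a presence
sign $s_k = \pm 1$:

$$H = \sum_k s_k h_k, \quad P = \sum_k s_k p_k, \quad
M = \sum_k s_k m_k.$$

Summing over all selected KOs (not only present ones) is the only
reading under which the canonical worked example is coherent: a KO with
$a_{het} = 0.1$ that is absent from the evaluated entity contributes
$-1 \times [-(0.5 - 0.1)] = +0.4$ to $H$ — its absence is evidence for
the mode it is characteristically absent from. A corollary is exact
antisymmetry: complementing an entity's presence set negates H, P
and M.

The composite heterotrophy index is

$$H_{ind} = \begin{cases} H - P & M - \max(H, P) < 50 \\
(H - P)/M & \text{otherwise,} \end{cases}$$

negative for phototroph-like, positive for heterotroph-like entities,
damped towards zero when the mixotrophy score dominates. The published
typesetting of this formula is corrupted; we read the numerator as
$\mathrm{sign}(H-P)\sqrt{(H-P)^2} = H-P$, which reproduces the
documented symmetric scale and sign convention, and keep the quadratic
alternative $\mathrm{sign}(H-P)(H-P)^2$ behind `form = "quadratic"`.
The descriptive bands of `classify_with_index()` (default cutoffs
±50, configurable) are reporting sugar only and never override the
forest's class.

# Co-occurrence network

Spearman correlations are computed for every unordered MAG pair over
shared samples (at least 3, otherwise missing), with midrank ties and
asymptotic p-values — the asymptotic form is used uniformly so results
do not change shape between tied and untied inputs. Edges then pass a
staged filter, in this order: (1) raw p below the Šidák cutoff
$1 - (1-\alpha)^{1/n}$ with $\alpha = 0.05$ and $n$ the number of
testable unordered pairs; (2) $|\rho|$ at or above the 90th percentile
of the survivors' $|\rho|$ — the percentile rule, not any fixed
constant, is the invariant worth keeping, since the corresponding
cutoff value is a property of each data set; (3) $|\rho|$ strictly
above 0.70; (4) prokaryote–prokaryote pairs dropped, keeping
eukaryote–eukaryote and eukaryote–prokaryote interactions. Stage counts
are recorded so the cascade is auditable. Negative correlations are
retained and weighted by $|\rho|$ (a `positive_only` flag restricts to
co-occurrence proper).

MAG pairs that are both near-identical (ANI ≥ 99%) and strongly
correlated (|ρ| > 0.70) are collapsed into cluster nodes (connected
components of that relation); intra-cluster edges vanish and parallel
edges keep the member pair of maximum $|\rho|$, preserving the
strongest detected association.

Communities come from multilevel (Louvain) modularity maximisation with
$|\rho|$ weights, seeded deterministically (node order is shuffled from
the seed). Connectedness within community $x$ is realized over possible
within-links, $C_{x,x} = e_x / \binom{n_x}{2}$; between communities the
default rule counts each MAG of either community the first time it
links to the other community — distinct incident nodes of the union —
divided by $\max(n_x, n_y)$ (a raw edge-count variant is available).
Note the off-diagonal quantity can exceed 1 for densely
cross-connected community pairs (it is bounded by
$(n_x+n_y)/\max(n_x,n_y) \le 2$); we do not cap it, since capping
would silently discard information and the diagonal is already a
proper fraction. Community–environment associations are Spearman
correlations of summed community abundance against each environmental
column, Bonferroni-adjusted over the comparisons actually made and
flagged at adjusted p < 0.01.

# Phylogenetic diversity and gain

Diversity of a leaf set is the total branch length of the minimal
spanning subtree connecting it, computed by an edge-split rule: an
edge is counted iff both sides of the split it induces contain a
selected leaf. This is root-invariant by construction (the stem edge
above the set's ancestor never separates selected leaves), matching the
convention of working on the unrooted edge set. Gain of a focal set
over a base set is $PD(\text{focal} \cup \text{base}) -
PD(\text{base})$, and additivity holds exactly. Percentages are
reported against the full tree length (diversity) and the combined-set
diversity (gain); since the reference convention for these denominators
is not fixed in the literature we also emit absolute branch-length
units so any denominator can be applied. Branch lengths are mandatory
in input trees — diversity is undefined without them — and a missing
length is an error, not a silent zero.

# Synthetic fixtures: what they emulate, and what they do not

`make_trophic_panel()` emulates a curated reference panel: 300
references per mode, 2,000 KOs of which 300 are mode-informative
(present with probability 0.9 within their mode, 0.1 outside) over a
0.5 background. These defaults give a signal strength at which a sound
selection-plus-forest pipeline should reach held-out accuracy ≥ 0.90 —
they are chosen to represent a clean version of the real task, where
annotation noise, phylogenetic correlation between references and
class imbalance all degrade the picture. Passing on this panel
demonstrates the machinery is correct, not that any particular real
accuracy will be attained.

`make_abundance_matrix()` plants two 8-member communities across 60
samples: members share a lognormal latent trajectory with 0.2 log-scale
member noise, background MAGs are independent lognormals, and
environmental covariates are noisy monotone transforms of the latents.
Lognormal latents mirror the heavy-tailed positive skew of real CPM
tables without claiming to model any particular survey; compositional
closure is applied (columns are normalised to CPM) so the fixture
carries the same constraint structure as real data. What it does not
emulate: spatial autocorrelation between samples, depth/size-fraction
structure, and sparsity from detection limits.

On these fixtures the community-recovery test applies the Šidák and
0.70 stages but not the percentile stage: a 90th-percentile cut is
meaningful on surveys with thousands of pairs, but on a 26-MAG toy
network it retains only the top dozen pairs by construction —
whatever the planted effect size — and tests nothing about community
detection. The percentile stage is exercised separately on its own
filter fixtures.

`make_toy_bins()` always emits one bin exactly at the length threshold
and one exactly at 90% eukaryotic content, so the strict-inequality
boundary behaviour is pinned by construction. A `scale` argument
shrinks bins (and the matching threshold) for fast fixtures; default
scale emits realistic Mbp-scale sequences.

# Determinism and numerical choices

Every stochastic step — panel generation, fold splits, forests, Louvain
node order — takes an explicit integer seed and is bit-reproducible
given it (forests run single-threaded for this reason). `run_all()`
writes a provenance manifest (versions, seed, thresholds, per-stage
record counts) and contains no timestamps, so identical configs produce
byte-identical output trees. Degenerate inputs are decided, not
accidental: all-zero abundance samples give zero columns with a
warning; singleton communities have within-connectedness 0 with a
warning; a taxonomy report whose root does not exceed the mapping
threshold returns the root with a warning; an empty reference set after
the 500-KO filter is an error.

The test suite's problem sizes (900 × 2,000 panel, 26 × 60 abundance
fixtures, ≤ 8-node exhaustive graph oracles, 100-tree additivity
sweeps) were chosen so the full suite completes in well under a minute
on a single core while still leaving no stage untested at its default
parameters.

# Known limitations

* ANI is consumed, never computed; the two-step sketch-then-align
  dereplication of production pipelines is collapsed into one matrix.
* The representative score omits strain heterogeneity and genome-size
  terms.
* Spearman p-values are asymptotic; for fewer than ~10 samples the
  Šidák stage is conservative at best.
* The trophic model treats references as exchangeable; it does not
  model phylogenetic non-independence among them.
* Exon merging reconciles coordinates only — no reading frames, intron
  phases or translations.
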