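---
title: "Metapangenomics at desk scale: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metapangenomics at desk scale: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapang)
```

# The analysis this package implements

Metapangenomics asks two coupled questions about a bacterial genus living
on a host: *what is the gene repertoire of its species* (the pangenome,
from isolate genome assemblies) and *where do those species actually live*
(read recruitment from environmental shotgun metagenomes, here human oral
sites). `metapang` implements the full chain at desk scale:

1. **Catalog curation.** Contigs shorter than 300 nt are removed and
   non-canonical letters become `N`. Genomes are kept when they come from
   a human host, are not duplicate strains, and have completeness >= 90%
   with contamination < 5%. Fragment-based average nucleotide identity
   (ANI) is computed between every pair, and the set is dereplicated so no
   two retained genomes share more than 98% ANI.
2. **Pangenome.** All-vs-all protein Smith–Waterman similarity, pruned by
   the *minbit* criterion (cross bitscore divided by the smaller
   self-bitscore, threshold 0.5), clustered with the Markov cluster
   algorithm (MCL) at inflation 10. Clusters present in every genome are
   *core*, in exactly one genome *singleton*, otherwise *accessory*.
   Genomes are ordered by Ward clustering (Euclidean distance) of their
   cluster-frequency rows.
3. **Phylogenomics.** Clusters occurring exactly once in every genome
   (single-copy core genes) are aligned, concatenated, trimmed of columns
   with more than 50% gaps, and summarised as a neighbor-joining tree on
   WAG-model maximum-likelihood distances. The tree is compared with the
   pangenome dendrogram by Robinson–Foulds distance.
4. **Read-recruitment profiling.** Per-base depth is accumulated from SAM
   alignments (reads are assumed competitively mapped upstream, one
   genome per read). A genome is *detected* in a sample when at least 50%
   of its positions have depth >= 1; a gene when at least 90% of its
   positions do. Abundance is the mean depth over the interquartile
   positions (depths ranked, middle half), normalised per sample over the
   reference set, and summed over the genomes of a species.
5. **Functional enrichment.** Metabolic modules (ordered steps, each a set
   of alternative orthologs) are scored per genome as the fraction of
   satisfied steps; a module is *complete* at >= 0.75. The
   complete/incomplete indicator is tested for association with
   site-specialist genome groups using the Rao score test of a logistic
   regression, with Benjamini–Hochberg q-values within each pairwise group
   comparison and an enrichment call at q <= 0.01.

Every threshold above is a named default of `selection_config()`,
`detection_config()`, or the relevant function argument; overriding them is
explicit and visible in calling code.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_contig_len` | 300 | nt | short contigs carry little signal and inflate fragment edge effects |
| `min_completeness` / `max_contamination` | 90 / 5 | % | standard draft-quality floor for reference sets |
| `derep_ani` | 0.98 | fraction | collapses near-identical assemblies while keeping distinct strains |
| `ani_fragment_len` | 1020 | nt | fragment-ANI convention; fragments behave like idealized long reads |
| fragment identity / coverage floors | 0.3 / 0.7 | fraction | discard spurious local hits before averaging identity |
| `minbit` threshold | 0.5 | fraction | removes weak protein matches before graph clustering |
| MCL `inflation` | 10 | — | high granularity: splits families connected only by weak bridges |
| `genome_breadth_min` | 0.5 | fraction | breadth, not depth, separates presence from cross-mapping noise |
| `gene_breadth_min` | 0.9 | fraction | stringent but tolerant of hypervariable gene ends |
| module completeness | 0.75 | fraction | a mostly-present pathway is functionally credible |
| enrichment `q_threshold` | 0.01 | — | conservative discovery cutoff across ~50 modules |

# Numerical and algorithmic choices

**ANI estimator.** Each query genome is cut into non-overlapping 1020-nt
windows; each window is aligned locally (match +1, mismatch −1, gap open 5,
extend 2) against the subject's contigs, on both strands. The reverse
strand is skipped when the forward hit already reaches identity >= 0.8 at
sufficient coverage — a reverse-strand alignment of the same fragment
cannot beat such a hit outside contrived palindromes. Windows passing the
coverage (>= 0.7) and identity (>= 0.3) floors contribute their identity to
the mean; the two directed estimates are averaged, making the result
symmetric by construction. On controlled substitution-only pairs the
estimator tracks true identity to within 0.005 across the 80–98% range.

**Dereplication.** The representative of a >98% ANI group is chosen
greedily: sort by completeness (desc), assembly length (desc), then
genome id; each unclaimed genome becomes a representative and claims all
genomes above the threshold. This is deterministic and favors the best
assemblies. Species-level clades use single-linkage components of the
>= 95% ANI graph, the conventional bacterial species boundary.

**Bitscores and minbit.** Raw Smith–Waterman scores (BLOSUM62, gap open
11 / extend 1) are converted to Karlin–Altschul bitscores with gapped
BLOSUM62 constants (lambda = 0.267, K = 0.041). Only score *ratios* enter
minbit, so raw scores give identical filtering; the bitscore form is kept
for interpretability. An optional shared-4-mer prefilter skips alignment of
pairs without a single common 4-mer — a BLAST-like seed heuristic that
cannot remove genuine homologs at the identity levels relevant here.
The boundary is inclusive: minbit = 0.5 survives.

**MCL.** Column-stochastic transition matrix from minbit weights with
self-loops equal to each node's maximum incident weight; expansion (matrix
square) alternates with element-wise inflation (power 10) and
renormalisation; entries below 1e-8 are pruned and convergence is declared
when the matrix changes by less than 1e-6 (cap 200 iterations). Clusters
are read from attractor rows; overlapping attractor supports merge, and
residual ties resolve toward the lowest gene id, so results are
deterministic for a fixed input order. Pruning matters: it removes the
vanishing influence a weak inter-family bridge exerts on a node, so
bridged families resolve cleanly instead of shedding boundary nodes as
spurious singletons.

**Center-star alignment.** Within-cluster alignment picks the member with
the maximum summed global-alignment score as the center, aligns every other
member to it pairwise, and merges by taking the maximum insertion length at
each center position. For two sequences this *is* the exact
Needleman–Wunsch alignment; for more it is a classic 2-approximation that
is accurate at the high within-cluster identities MCL produces. Ungapping
any output row returns the input sequence unchanged — asserted in tests.

**Trimming and trees.** Column trimming removes columns with gap fraction
strictly above 0.5 ('X' counts as residue, not gap) and is idempotent.
The tree is neighbor joining on WAG maximum-likelihood distances with
negative branch lengths clamped to zero; its acceptance surface is
topology recovery on synthetic data, not likelihood. Site-resampling
bootstrap over the NJ pipeline is available but off by default.

**Interquartile mean.** Depths are sorted ascending and 0-based indices
`[floor(L/4), ceil(3L/4))` are averaged — exactly the middle half when L is
divisible by 4, at least half otherwise. All "at least" thresholds in the
detection rules are inclusive.

**Abundance denominator.** The per-sample normaliser defaults to the
summed interquartile mean of *all* reference genomes; a
`denominator = "detected"` switch restricts it to detected genomes. Both
readings appear in practice; the default keeps undetected genomes in the
denominator, so their (small) residual coverage is not redistributed.

**Enrichment test.** The Rao score statistic of `presence ~ group` against
the intercept-only logistic model equals the Pearson chi-square of the
underlying contingency table and never requires the alternative model's
MLE to be finite, so perfectly separated modules (the interesting ones) are
handled without ad hoc corrections. Patterns identical across all genomes
carry no information and are reported as score 0, p 1. q-values are BH
within one pairwise comparison; comparisons are not pooled.

# What the generator simulates — and what it does not

`simulate_catalog()` builds genomes as concatenated 330-nt gene cassettes
(300-nt gene + 30-nt intergenic tail, mutated as a unit): core families in
every genome, accessory families in all genomes of a random proper species
subset, and private singleton cassettes appended per genome. Divergence is
i.i.d. substitution with *count-fixed* draws — exactly `round(rate * L)`
positions mutate, with random positions and target bases — so realized ANI
tracks the configured targets tightly even on 10-kb genomes. Rates are
solved analytically from the within-species (default 0.965) and
between-species (default 0.85) ANI targets, placing clades clearly above
and below the 95% species boundary and below the 98% dereplication cutoff,
as in a curated post-dereplication reference set.

`simulate_metagenomes()` draws error-free reads uniformly along each
genome with expected depth = site weight × `depth_per_site` (default 50×),
already assigned to their source genome — idealized competitive mapping.
`simulate_annotations()` plants `n_planted_enriched` modules complete only
in a target species group and makes the rest complete independently with
probability 1/2.

Passing tests on this generator demonstrates *method correctness* —
thresholds applied as specified, estimators tracking planted truth — not
robustness to the things real data add: sequencing error, strain mixtures
within species, mobile elements, cross-mapping between conserved genes,
uneven coverage (GC bias), or incomplete/incorrect ortholog annotation.
The generator deliberately omits within-species strain structure, so
sub-species site specialisation is out of scope.

# Problem sizes and statistical design

The bundled analyses and tests run on 3 species × 2 genomes of ~9.9 kb
(catalog and profiling stages), 4 oral sites × 2–3 samples at 50× depth,
and 2 species × 10 genomes for enrichment power — sizes chosen so each
stage's statistics are informative: ~6 accepted ANI fragments per
between-clade pair keep the realized-ANI check tight, 50× depth makes
breadth-based detection essentially noise-free, and 10 genomes per group
give the score test power at q <= 0.01 for fully separated modules.

The type-I-error simulation uses 2 groups × 30 genomes with presence
probability 1/2 across 1,000 items. The group size was fixed by exact
enumeration of the score-test null: at 15 per group the chi-square
approximation is conservative (true rejection rate 0.0456 at nominal
0.05), while at 30 per group it is 0.0519 — close enough to nominal that a
1,000-item empirical rate sits comfortably inside its 99% binomial band.

# Known limitations

- ANI is fragment-based with fixed scoring; it is not a drop-in
  replacement for k-mer or BLAST-based tools on real draft genomes with
  repeats and contamination.
- The center-star aligner is not a progressive MSA; at low within-cluster
  identity (< ~50%) its gap placement degrades before its score does.
- The NJ/WAG tree has no branch support unless bootstrap is enabled, and
  no model selection.
- The profiler trusts the upstream mapper's single-assignment of reads;
  it never reassigns multi-mapping reads.
- Module definitions are flat OR-of-alternatives steps; nested boolean
  pathway definitions are not parsed.
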