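# metapang

Desk-scale **metapangenomics** for host-associated bacterial genera: who is
in the genus (pangenome structure from isolate genomes), where each species
lives (read recruitment across body sites), and which metabolic capabilities
distinguish the site specialists.

The package is aimed at microbiome researchers who want the full analysis
chain — genome catalog curation, pangenome construction, phylogenomics,
metagenomic profiling, and functional enrichment — as small, tested,
composable R functions, together with a seeded synthetic-data generator so
the whole pipeline can be exercised and validated without any external
downloads.

## The methods in brief

- **ANI dereplication.** Fragment-based average nucleotide identity: the
  query is cut into 1020-nt windows, each aligned locally against the
  subject (both strands); windows passing coverage >= 0.7 and identity
  >= 0.3 contribute to the mean, and directed estimates are averaged.
  Genomes sharing > 98% ANI collapse to their best assembly; single-linkage
  components at >= 95% define species-level clades.
- **Pangenome.** All-vs-all protein Smith–Waterman (BLOSUM62) scores are
  normalised as *minbit* = bitscore / min(self bitscores), pruned at 0.5,
  and clustered by MCL (inflation 10). Clusters present in every genome are
  core; in exactly one, singletons; otherwise accessory. Genomes cluster by
  Ward linkage on Euclidean distances over cluster frequencies.
- **Phylogenomics.** Single-copy core clusters are center-star aligned,
  concatenated, trimmed of columns with > 50% gaps, and summarised by
  neighbor joining on WAG distances; tree vs dendrogram agreement is
  measured by Robinson–Foulds distance.
- **Profiling.** Per-base depth from SAM alignments. Detection: breadth of
  coverage >= 50% for genomes, >= 90% for genes, at depth >= 1. Abundance:
  mean depth over the interquartile (Q2–Q3) positions, normalised per
  sample and summed per species.
- **Enrichment.** Module completeness (fraction of satisfied steps,
  complete at >= 0.75), Rao score test of a logistic presence ~ group
  model for every pairwise group comparison, BH q-values, calls at
  q <= 0.01.

## Worked example

The `analysis/` directory is a numbered workflow over a simulated genus of
3 species-level clades (2 genomes each) with planted site tropism and two
planted site-specific metabolic modules:

```sh
Rscript analysis/01_simulate.R    # genomes, SAMs, annotations + ground truth
Rscript analysis/02_catalog.R    # ANI, dereplication, species clades
Rscript analysis/03_pangenome.R  # minbit + MCL pangenome, dendrogram
Rscript analysis/04_phylogeny.R  # SCG supermatrix + NJ tree
Rscript analysis/05_profile.R    # detection + abundance per oral site
Rscript analysis/06_enrichment.R # module completeness + enrichment
```

Output actually printed by the run (abridged):

```
selected 6 of 6 genomes
dereplication at 98.0% ANI kept 6 representatives
3 species-level clades at the 95% ANI boundary
pangenome: 89 gene clusters (8 core, 27 accessory, 54 singleton)
8 single-copy core clusters over 6 genomes (48 genes)
supermatrix: 6 taxa x 800 columns after trimming
Robinson-Foulds distance SCG tree vs pangenome dendrogram: 0
dominant species per site:
  KG    S3 (mean relative abundance 1.00)
  SUBP  S2 (mean relative abundance 1.00)
  SUPP  S1 (mean relative abundance 1.00)
  TD    S1 (mean relative abundance 1.00)
power run (10 genomes/group): flagged M00001, M00002; planted M00001, M00002
```

Reading this: the three planted clades are recovered from ANI alone; the
single-copy-core phylogeny and the gene-frequency dendrogram agree exactly
(RF = 0); each species is detected only at its planted oral sites (S1 is a
plaque/tongue specialist in this simulation); and the two planted
metabolic modules — and nothing else — are flagged at q <= 0.01 once group
sizes give the test power. Per-stage tables land under `results/`.

Library use is equally direct:

```r
library(metapang)
cfg <- simulation_config(seed = 1, n_species = 3, genomes_per_species = 2)
sim <- simulate_catalog(cfg)
ani <- ani_matrix(sim$catalog)
ani_species_groups(names(sim$catalog), ani)  # clade label per genome
```

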