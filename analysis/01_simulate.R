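#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system — a genus of 3 species-level
# clades (2 genomes each, ~9.9 kb), site-structured metagenomes over 4 oral
# sites, and 50 metabolic modules with 2 planted site-specific ones.
# Writes the genome FASTA/manifest, per-sample SAM files, annotation and
# module tables under results/sim/.

library(metapang)

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 20260925L, n_species = 3,
                         genomes_per_species = 2, genome_len = 9900)
sim <- simulate_catalog(cfg)
write_catalog(sim$catalog, file.path(out, "genomes.fa"),
              file.path(out, "genome_manifest.tsv"))
write.table(sim$genes[, c("gene_id", "genome_id", "contig_id", "start",
                          "stop", "strand")],
            file.path(out, "gene_calls.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

mg <- simulate_metagenomes(cfg, sim, samples_per_site = 3)
clens <- unlist(lapply(unname(sim$catalog),
                       function(g) setNames(nchar(g$contigs),
                                            names(g$contigs))))
for (sid in names(mg$samples)) {
  write_sam(mg$samples[[sid]], clens, file.path(out, paste0(sid, ".sam")))
}
write.table(mg$manifest, file.path(out, "sample_manifest.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

ann <- simulate_annotations(cfg, sim)
write.table(ann$annotations, file.path(out, "annotations.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
jsonlite::write_json(
  list(modules = lapply(ann$modules, function(m) m$steps),
       planted = ann$planted, target_species = ann$target_species,
       species = as.list(sim$truth$species),
       tropism = cfg$tropism),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE)

message(sprintf("simulated %d genomes (%d genes), %d samples, %d modules",
                length(sim$catalog), nrow(sim$genes),
                length(mg$samples), length(ann$modules)))
message("planted enriched modules: ", paste(ann$planted, collapse = ", "))
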