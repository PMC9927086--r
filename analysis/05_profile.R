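#!/usr/bin/env Rscript
# Stage 5: metagenomic read-recruitment profiling — per-base coverage from
# the per-sample SAM files, breadth >= 50% genome detection, interquartile
# mean-depth relative abundance, and the species roll-up per oral site.

library(metapang)

out <- "results/profile"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

catalog <- read_catalog("results/sim/genomes.fa",
                        "results/sim/genome_manifest.tsv")
rep_ids <- readLines("results/catalog/representatives.txt")
reps <- catalog[rep_ids]
manifest <- load_sample_manifest("results/sim/sample_manifest.tsv")
message(sprintf("%d samples over %d oral sites", manifest$total,
                sum(manifest$per_site > 0)))

rep_contigs <- unlist(lapply(reps, function(g) names(g$contigs)))
cfg <- detection_config()
tabs <- list()
for (i in seq_len(nrow(manifest$samples))) {
  sid <- manifest$samples$sample_id[i]
  aln <- read_sam(file.path("results/sim", paste0(sid, ".sam")))
  aln <- aln[aln$rname %in% rep_contigs, , drop = FALSE]
  profs <- coverage_from_alignments(aln, reps, sample_id = sid)
  tabs[[sid]] <- relative_abundance(profs, cfg)
}
abundance <- do.call(rbind, tabs)
rownames(abundance) <- NULL
write.table(abundance, file.path(out, "abundance.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

detection <- xtabs(detected ~ genome_id + sample_id, data = abundance) > 0
write.table(detection * 1L, file.path(out, "detection.tsv"), sep = "\t",
            quote = FALSE, col.names = NA)

species_map <- vapply(reps, `[[`, character(1), "species")
names(species_map) <- rep_ids
rollup <- species_rollup(abundance, species_map)
rollup$oral_site <- manifest$samples$oral_site[
  match(rollup$sample_id, manifest$samples$sample_id)]
write.table(rollup, file.path(out, "species_abundance.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

dominant <- aggregate(rel_abundance ~ oral_site + species, rollup, mean)
dominant <- dominant[order(dominant$oral_site, -dominant$rel_abundance), ]
top <- do.call(rbind, lapply(split(dominant, dominant$oral_site),
                             function(d) d[1, ]))
message("dominant species per site:")
for (i in seq_len(nrow(top))) {
  message(sprintf("  %-5s %s (mean relative abundance %.2f)",
                  top$oral_site[i], top$species[i], top$rel_abundance[i]))
}
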