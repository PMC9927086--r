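#' Load and tally a sample manifest
#'
#' Reads a TSV with columns sample_id, oral_site, total_reads (mapped_reads
#' optional), validates the site vocabulary (\code{\link{ORAL_SITES}}) and
#' sample uniqueness, and reports per-site counts. Samples with zero mapped
#' reads draw a warning rather than an error (some sites have only a
#' handful of samples and must not break aggregation).
#'
#' @param path Path to a manifest TSV (or a data.frame passed through).
#' @return List: \code{samples} (data.frame), \code{per_site} (named
#'   integer counts), \code{total} (grand total).
#' @export
load_sample_manifest <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "oral_site", "total_reads")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("manifest lacks column(s): ",
                             paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    return(list(samples = df,
                per_site = stats::setNames(integer(length(ORAL_SITES)),
                                           ORAL_SITES),
                total = 0L))
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0) stop("duplicate sample_id(s): ",
                            paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(df$oral_site), ORAL_SITES)
  if (length(bad) > 0) {
    stop("unknown oral site label(s): ", paste(bad, collapse = ", "),
         " (vocabulary: ", paste(ORAL_SITES, collapse = ", "), ")")
  }
  if ("mapped_reads" %in% names(df)) {
    if (any(df$mapped_reads > df$total_reads)) {
      stop("mapped_reads exceeds total_reads for sample(s): ",
           paste(df$sample_id[df$mapped_reads > df$total_reads],
                 collapse = ", "))
    }
    if (any(df$mapped_reads == 0)) {
      warning("sample(s) with zero mapped reads: ",
              paste(df$sample_id[df$mapped_reads == 0], collapse = ", "))
    }
  }
  per_site <- stats::setNames(integer(length(ORAL_SITES)), ORAL_SITES)
  tab <- table(df$oral_site)
  per_site[names(tab)] <- as.integer(tab)
  list(samples = df, per_site = per_site, total = nrow(df))
}

#' Write a genome catalog as multi-FASTA plus manifest TSV
#'
#' @param catalog List of \code{genome_record}s.
#' @param fasta_path,manifest_path Output paths.
#' @return Invisibly, the manifest data.frame.
#' @export
write_catalog <- function(catalog, fasta_path, manifest_path) {
  seqs <- character(0)
  for (g in catalog) {
    s <- g$contigs
    names(s) <- paste(g$genome_id, names(s), sep = "|")
    seqs <- c(seqs, s)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  manifest <- do.call(rbind, lapply(catalog, function(g) {
    data.frame(genome_id = g$genome_id, species = g$species, host = g$host,
               oral = g$oral, completeness = g$completeness,
               contamination = g$contamination,
               duplicate_of = g$duplicate_of, stringsAsFactors = FALSE)
  }))
  utils::write.table(manifest, manifest_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(manifest)
}

#' Read a genome catalog written by \code{\link{write_catalog}}
#'
#' FASTA headers carry \code{genome_id|contig_id}; metadata comes from the
#' manifest TSV.
#'
#' @param fasta_path,manifest_path Input paths.
#' @return List of \code{genome_record}s.
#' @export
read_catalog <- function(fasta_path, manifest_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  gid <- vapply(parts, `[[`, character(1), 1)
  cid <- vapply(parts, `[[`, character(1), 2)
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    sel <- gid == row$genome_id
    contigs <- stats::setNames(as.character(seqs[sel]), cid[sel])
    out[[row$genome_id]] <- genome_record(
      row$genome_id, contigs, species = row$species, host = row$host,
      oral = row$oral, completeness = row$completeness,
      contamination = row$contamination,
      duplicate_of = if (is.na(row$duplicate_of) ||
                         row$duplicate_of == "") NA_character_
                     else row$duplicate_of)
  }
  out
}

#' Run the full metapangenomic pipeline on in-memory inputs
#'
#' Chains the five stages in order: catalog curation (clean, select,
#' all-pairs ANI, dereplication), pangenome (protein similarity, minbit,
#' MCL, classification, dendrogram), phylogenomics (SCG extraction,
#' center-star alignment, trim, NJ tree, tree comparison), metagenome
#' profiling (coverage, detection, interquartile abundance, species
#' roll-up) and module enrichment. Stages whose inputs are absent (e.g. no
#' alignments supplied) are skipped. All stage outputs are returned and,
#' when \code{outdir} is given, written as plain-text TSV/Newick artifacts.
#'
#' @param catalog List of \code{genome_record}s.
#' @param samples Named list of alignment data.frames (one per sample), or
#'   NULL to skip profiling.
#' @param sample_manifest Manifest data.frame for \code{samples}.
#' @param annotations Annotation data.frame, or NULL to skip enrichment.
#' @param modules Named list of module definitions.
#' @param groups Named genome -> group labels for enrichment (defaults to
#'   the ANI species groups).
#' @param genes Gene-call data.frame for the representative genomes (see
#'   \code{\link{gene_calls}}), or NULL to skip the pangenome and
#'   phylogenomics stages.
#' @param sel_cfg,det_cfg Stage configurations.
#' @param minbit,inflation,q_threshold,module_threshold Stage thresholds
#'   (defaults 0.5, 10, 0.01, 0.75).
#' @param outdir Optional output directory for TSV artifacts.
#' @return A list with per-stage results: \code{selected}, \code{ani},
#'   \code{representatives}, \code{species_groups}, \code{edges},
#'   \code{membership}, \code{matrix}, \code{classes}, \code{dendrogram},
#'   \code{scg}, \code{supermatrix}, \code{tree}, \code{tree_comparison},
#'   \code{abundance}, \code{detection}, \code{species_abundance},
#'   \code{completeness}, \code{enrichment}.
#' @export
run_pipeline <- function(catalog, samples = NULL, sample_manifest = NULL,
                         annotations = NULL, modules = NULL, groups = NULL,
                         sel_cfg = selection_config(),
                         det_cfg = detection_config(),
                         minbit = 0.5, inflation = 10,
                         q_threshold = 0.01, module_threshold = 0.75,
                         genes = NULL, outdir = NULL) {
  out <- list()
  if (!is.null(sample_manifest)) {
    out$sample_tally <- load_sample_manifest(sample_manifest)
  }
  cleaned <- lapply(catalog, clean_contigs, cfg = sel_cfg)
  out$selected <- select_genomes(cleaned, sel_cfg)
  out$ani <- ani_matrix(out$selected, sel_cfg)
  out$representatives <- dereplicate(out$selected, out$ani, sel_cfg)
  rep_ids <- vapply(out$representatives, `[[`, character(1), "genome_id")
  out$species_groups <- ani_species_groups(rep_ids, out$ani)

  if (!is.null(genes)) {
    genes <- genes[genes$genome_id %in% rep_ids, , drop = FALSE]
    out$edges <- pairwise_scores(genes)
    filtered <- minbit_filter(out$edges, minbit)
    out$membership <- mcl_cluster(filtered, genes$gene_id, inflation)
    out$matrix <- pangenome_matrix(out$membership, genes)
    out$classes <- classify_clusters(out$matrix)
    out$dendrogram <- genome_dendrogram(out$matrix)

    scg <- extract_scg(out$matrix)
    out$scg <- scg
    if (length(scg$clusters) >= 1 && nrow(out$matrix) >= 3) {
      members <- attr(out$matrix, "members")
      prot <- stats::setNames(genes$protein, genes$gene_id)
      gmap <- stats::setNames(genes$genome_id, genes$gene_id)
      alns <- lapply(scg$clusters, function(cl) {
        ids <- members[[cl]]
        align_cluster(stats::setNames(prot[ids], gmap[ids]))
      })
      names(alns) <- scg$clusters
      out$supermatrix <- concatenate_and_trim(alns)
      out$tree <- build_tree(out$supermatrix)
      out$tree_comparison <- compare_trees(
        out$tree, ape::as.phylo(out$dendrogram$hclust))
    }
  }

  if (!is.null(samples)) {
    rep_set <- out$representatives
    rep_contigs <- unlist(lapply(rep_set, function(g) names(g$contigs)))
    ab <- list()
    for (sid in names(samples)) {
      aln <- samples[[sid]]
      # only reads mapping to the dereplicated reference are profiled
      aln <- aln[aln$rname %in% rep_contigs, , drop = FALSE]
      profs <- coverage_from_alignments(aln, rep_set, sample_id = sid)
      ab[[sid]] <- relative_abundance(profs, det_cfg)
    }
    out$abundance <- do.call(rbind, ab)
    rownames(out$abundance) <- NULL
    det <- out$abundance
    out$detection <- stats::xtabs(detected ~ genome_id + sample_id,
                                  data = det) > 0
    sp_map <- vapply(rep_set, function(g) {
      if (is.na(g$species)) paste0("group", out$species_groups[g$genome_id])
      else g$species
    }, character(1))
    names(sp_map) <- vapply(rep_set, `[[`, character(1), "genome_id")
    out$species_abundance <- species_rollup(out$abundance, sp_map)
  }

  if (!is.null(annotations) && !is.null(modules)) {
    ann <- annotations[annotations$genome_id %in% rep_ids, , drop = FALSE]
    out$completeness <- completeness_matrix(ann, modules, module_threshold)
    if (is.null(groups)) {
      groups <- stats::setNames(
        paste0("group", out$species_groups[rownames(out$completeness$complete)]),
        rownames(out$completeness$complete))
    }
    out$enrichment <- enriched_modules(out$completeness$complete, groups,
                                       q_threshold)
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out$ani, file.path(outdir, "ani.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    writeLines(vapply(out$representatives, `[[`, character(1), "genome_id"),
               file.path(outdir, "representatives.txt"))
    if (!is.null(out$matrix)) {
      utils::write.table(out$matrix, file.path(outdir, "pangenome_matrix.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      writeLines(out$dendrogram$newick, file.path(outdir, "dendrogram.nwk"))
    }
    if (!is.null(out$tree)) {
      ape::write.tree(out$tree, file.path(outdir, "scg_tree.nwk"))
    }
    if (!is.null(out$abundance)) {
      utils::write.table(out$abundance, file.path(outdir, "abundance.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(out$enrichment)) {
      utils::write.table(out$enrichment, file.path(outdir, "enrichment.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  out
}
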