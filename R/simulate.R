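# Stop-free codons used to build genes whose translation has no premature
# stop (mutations may still create one; translation maps '*' to 'X').
.CODONS <- {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

# Substitution probability per lineage giving pairwise identity I when two
# lineages mutate independently from a common ancestor (uniform choice
# among the 3 alternative bases): I = (1-s)^2 + s^2/3.
.rate_for_identity <- function(I) {
  stopifnot(I > 0.25, I <= 1)
  0.75 * (1 - sqrt(1 - (4 / 3) * (1 - I)))
}

# Count-fixed substitution: exactly round(rate * L) positions are replaced
# by a uniformly drawn different base. Fixing the count (rather than
# Bernoulli thinning) removes binomial noise so realized divergence tracks
# the ANI targets tightly even on short genomes.
.mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  n_hit <- round(rate * length(chars))
  if (n_hit > 0) {
    hit <- sample.int(length(chars), n_hit)
    bases <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(x) {
      sample(setdiff(bases, x), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

.random_gene <- function(n_codons) {
  paste(sample(.CODONS, n_codons, replace = TRUE), collapse = "")
}

# Batch translation; premature stops and fuzzy codons become 'X'.
.translate_genes <- function(nts) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nts), if.fuzzy.codon = "X"))
  gsub("\\*", "X", aa)
}

#' Simulation configuration
#'
#' Defines the synthetic study conditions: a genus of several species-level
#' clades with high within-clade and low between-clade ANI, shared
#' core/accessory gene-family structure plus per-genome singletons, a set
#' of body sites with species-level tropism, and module/function plantings
#' for enrichment testing.
#'
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @param n_species,genomes_per_species Clade structure (defaults 4 x 3).
#' @param genome_len Approximate genome length in nt (default 9900, i.e.
#'   30 gene cassettes of 330 nt).
#' @param within_species_ani,between_species_ani Target pairwise ANI
#'   fractions (defaults 0.965 / 0.85: clearly above the 95% species
#'   boundary within clades, clearly below it between, and below the 98%
#'   dereplication threshold as in a curated post-dereplication reference
#'   set).
#' @param core_frac,accessory_frac,singleton_frac Fractions of each
#'   genome's gene complement drawn from core, clade-restricted accessory,
#'   and genome-private singleton families; must sum to 1.
#' @param n_sites Number of body sites (default 4, labelled from the
#'   9-site oral vocabulary).
#' @param tropism Named list: species -> integer site indices the species
#'   recruits reads from; default assigns species round-robin to single
#'   sites.
#' @param depth_per_site Expected per-genome depth (x) at a site where the
#'   genome's weight is 1; default 50.
#' @param read_len Read length in nt, default 100.
#' @param n_modules,n_planted_enriched Module count and how many are made
#'   complete only in the first species group (defaults 50 / 2).
#' @return List of class \code{simulation_config}.
#' @export
simulation_config <- function(seed = 1L, n_species = 4L,
                              genomes_per_species = 3L,
                              genome_len = 9900L,
                              within_species_ani = 0.965,
                              between_species_ani = 0.85,
                              core_frac = 0.25, accessory_frac = 0.45,
                              singleton_frac = 0.30,
                              n_sites = 4L, tropism = NULL,
                              depth_per_site = 50, read_len = 100L,
                              n_modules = 50L, n_planted_enriched = 2L) {
  fr <- c(core_frac, accessory_frac, singleton_frac)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("core, accessory and singleton fractions must be >= 0 and sum to 1")
  }
  if (within_species_ani <= between_species_ani) {
    stop("within-species ANI must exceed between-species ANI")
  }
  if (n_planted_enriched > n_modules) {
    stop("cannot plant more enriched modules than modules")
  }
  if (is.null(tropism)) {
    # round-robin both ways so every species has a site and every site a
    # species (specialists: one or few sites each)
    tropism <- lapply(seq_len(n_species),
                      function(i) ((i - 1L) %% n_sites) + 1L)
    for (j in seq_len(n_sites)) {
      owner <- ((j - 1L) %% n_species) + 1L
      tropism[[owner]] <- sort(unique(c(tropism[[owner]], j)))
    }
    names(tropism) <- sprintf("S%d", seq_len(n_species))
  }
  structure(list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    genomes_per_species = as.integer(genomes_per_species),
    genome_len = as.integer(genome_len),
    within_species_ani = within_species_ani,
    between_species_ani = between_species_ani,
    core_frac = core_frac, accessory_frac = accessory_frac,
    singleton_frac = singleton_frac,
    n_sites = as.integer(n_sites), tropism = tropism,
    depth_per_site = depth_per_site, read_len = as.integer(read_len),
    n_modules = as.integer(n_modules),
    n_planted_enriched = as.integer(n_planted_enriched)
  ), class = "simulation_config")
}

#' Simulate a genome catalog with known clade and gene-family structure
#'
#' Genomes are concatenations of 330-nt gene cassettes (300-nt gene + 30-nt
#' intergenic tail, mutated as a unit). Core families occur in every
#' genome, accessory families in all genomes of a random nonempty proper
#' subset of species, and singleton families are private random cassettes
#' appended at the end of each genome. Nucleotide divergence is i.i.d.
#' substitution at rates solved analytically from the within- and
#' between-species ANI targets, so realized ANI tracks the targets.
#'
#' @param cfg A \code{\link{simulation_config}}.
#' @return List: \code{catalog} (genome_records), \code{genes} (gene-call
#'   data.frame), \code{truth} (species map, per-gene family map, family
#'   categories).
#' @export
simulate_catalog <- function(cfg) {
  set.seed(cfg$seed)
  gene_nt <- 300L; tail_nt <- 30L; cassette <- gene_nt + tail_nt
  slots <- max(4L, cfg$genome_len %/% cassette)
  n_core <- max(1L, round(cfg$core_frac * slots))
  n_sing <- round(cfg$singleton_frac * slots)
  n_acc_per_genome <- slots - n_core - n_sing
  s_within <- .rate_for_identity(cfg$within_species_ani)
  rho <- .rate_for_identity(cfg$between_species_ani)
  # exact two-round composition: after species (r) and genome (s) rounds the
  # probability of sitting off the ancestral base is r + s - (4/3) r s
  s_species <- max(0, (rho - s_within) / (1 - (4 / 3) * s_within))
  species <- sprintf("S%d", seq_len(cfg$n_species))

  # ancestral cassettes for core families and a shared accessory pool
  n_acc_pool <- max(n_acc_per_genome * 2L, n_acc_per_genome + 2L)
  fam_ids <- c(sprintf("FAM_core_%03d", seq_len(n_core)),
               if (n_acc_pool > 0) sprintf("FAM_acc_%03d", seq_len(n_acc_pool)))
  ancestors <- stats::setNames(vapply(fam_ids, function(f) {
    paste0(.random_gene(gene_nt / 3L),
           paste(sample(c("A", "C", "G", "T"), tail_nt, replace = TRUE),
                 collapse = ""))
  }, character(1)), fam_ids)
  # accessory families live in a random nonempty proper species subset
  acc_species <- lapply(seq_len(n_acc_pool), function(i) {
    k <- sample(seq_len(max(1L, cfg$n_species - 1L)), 1)
    sort(sample(species, k))
  })
  names(acc_species) <- grep("^FAM_acc_", fam_ids, value = TRUE)

  catalog <- list(); gene_rows <- list(); truth_species <- character(0)
  gene_family <- character(0)
  for (sp_i in seq_along(species)) {
    sp <- species[sp_i]
    sp_anc <- vapply(ancestors, .mutate, character(1), rate = s_species)
    carries <- names(acc_species)[vapply(acc_species, function(s) sp %in% s,
                                         logical(1))]
    carries <- utils::head(carries, n_acc_per_genome)
    fam_order <- c(grep("^FAM_core_", fam_ids, value = TRUE), carries)
    for (g_i in seq_len(cfg$genomes_per_species)) {
      gid <- sprintf("%s_g%d", sp, g_i)
      cassettes <- vapply(sp_anc[fam_order], .mutate, character(1),
                          rate = s_within)
      fams <- fam_order
      if (n_sing > 0) {
        sing <- vapply(seq_len(n_sing), function(k) {
          paste0(.random_gene(gene_nt / 3L),
                 paste(sample(c("A", "C", "G", "T"), tail_nt,
                              replace = TRUE), collapse = ""))
        }, character(1))
        sing_ids <- sprintf("FAM_sing_%s_%03d", gid, seq_len(n_sing))
        cassettes <- c(cassettes, sing)
        fams <- c(fams, sing_ids)
      }
      contig <- paste(cassettes, collapse = "")
      contig_id <- paste0(gid, "_c1")
      rec <- genome_record(gid, stats::setNames(contig, contig_id),
                           species = sp, host = "human", oral = TRUE,
                           completeness = round(stats::runif(1, 92, 99), 1),
                           contamination = round(stats::runif(1, 0, 2), 2))
      catalog[[gid]] <- rec
      truth_species[gid] <- sp
      starts <- (seq_along(cassettes) - 1L) * cassette + 1L
      gids <- sprintf("%s_gene%03d", gid, seq_along(cassettes))
      prot <- .translate_genes(substring(contig, starts,
                                         starts + gene_nt - 1L))
      gene_rows[[gid]] <- gene_calls(
        gene_id = gids, genome_id = gid, contig_id = contig_id,
        start = starts, stop = starts + gene_nt - 1L, strand = "+",
        protein = prot)
      gene_family[gids] <- fams
    }
  }
  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL
  list(catalog = catalog, genes = genes,
       truth = list(species = truth_species, gene_family = gene_family,
                    accessory_species = acc_species))
}

#' Simulate site-structured metagenomic alignments
#'
#' Reads are drawn uniformly along each genome with expected depth =
#' per-genome weight x \code{depth_per_site}; weight defaults to 1 at the
#' genome's species' tropism sites and 0 elsewhere (idealized competitive
#' mapping: every read is reported against its source genome). Site labels
#' come from the 9-site oral vocabulary.
#'
#' @param cfg A \code{\link{simulation_config}}.
#' @param sim A catalog from \code{\link{simulate_catalog}}.
#' @param samples_per_site Number of samples per site, default 3.
#' @param weights Optional genomes x sites numeric matrix overriding the
#'   tropism-derived weights.
#' @return List: \code{samples} (named list of alignment data.frames),
#'   \code{manifest} (sample_id, oral_site, total_reads, mapped_reads),
#'   \code{weights} (the genomes x sites matrix used).
#' @export
simulate_metagenomes <- function(cfg, sim, samples_per_site = 3L,
                                 weights = NULL) {
  set.seed(cfg$seed + 1L)
  sites <- ORAL_SITES[seq_len(cfg$n_sites)]
  gids <- names(sim$catalog)
  if (is.null(weights)) {
    weights <- matrix(0, length(gids), length(sites),
                      dimnames = list(gids, sites))
    for (gid in gids) {
      sp <- sim$truth$species[[gid]]
      weights[gid, cfg$tropism[[sp]]] <- 1
    }
  }
  samples <- list(); manifest <- list()
  for (s_i in seq_along(sites)) {
    site <- sites[s_i]
    if (all(weights[, s_i] == 0) && cfg$depth_per_site > 0) {
      stop("no genome has positive weight at site ", site)
    }
    for (r in seq_len(samples_per_site)) {
      sample_id <- sprintf("%s_%02d", site, r)
      aln <- list()
      for (gid in gids) {
        w <- weights[gid, s_i]
        if (w <= 0 || cfg$depth_per_site <= 0) next
        rec <- sim$catalog[[gid]]
        L <- genome_length(rec)
        n_reads <- round(w * cfg$depth_per_site * L / cfg$read_len)
        if (n_reads == 0) next
        starts <- sample.int(L - cfg$read_len + 1L, n_reads, replace = TRUE)
        aln[[gid]] <- data.frame(
          qname = sprintf("%s_%s_r%06d", sample_id, gid, seq_len(n_reads)),
          flag = 0L, rname = names(rec$contigs)[1], pos = starts,
          cigar = sprintf("%dM", cfg$read_len), stringsAsFactors = FALSE)
      }
      aln <- if (length(aln) > 0) do.call(rbind, aln) else
        data.frame(qname = character(), flag = integer(),
                   rname = character(), pos = integer(),
                   cigar = character(), stringsAsFactors = FALSE)
      rownames(aln) <- NULL
      mapped <- nrow(aln)
      samples[[sample_id]] <- aln
      manifest[[sample_id]] <- data.frame(
        sample_id = sample_id, oral_site = site,
        total_reads = max(mapped, round(mapped / 0.065)),
        mapped_reads = mapped, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  list(samples = samples, manifest = manifest, weights = weights)
}

#' Simulate functional annotations and module definitions
#'
#' Builds \code{n_modules} four-step modules (each step a set of 1-2
#' alternative KO accessions). Planted modules are complete only in the
#' target species group (others carry half the steps); neutral modules are
#' complete in each genome independently with probability 1/2 (carrying
#' half the steps otherwise), giving a null with no group association when
#' nothing is planted.
#'
#' @param cfg A \code{\link{simulation_config}}.
#' @param sim A catalog from \code{\link{simulate_catalog}}.
#' @param target_species Species whose genomes carry the planted modules
#'   complete; default the first species.
#' @return List: \code{annotations} (data.frame genome_id, gene_id,
#'   source, accession, description), \code{modules} (named list),
#'   \code{planted} (module ids), \code{target_species}.
#' @export
simulate_annotations <- function(cfg, sim, target_species = NULL) {
  set.seed(cfg$seed + 2L)
  if (is.null(target_species)) target_species <- "S1"
  gids <- names(sim$catalog)
  n_steps <- 4L
  ko_counter <- 0L
  modules <- list()
  for (m in seq_len(cfg$n_modules)) {
    steps <- lapply(seq_len(n_steps), function(s) {
      n_alt <- sample(1:2, 1)
      ko_counter <<- ko_counter + n_alt
      sprintf("K%05d", seq.int(ko_counter - n_alt + 1L, ko_counter))
    })
    mid <- sprintf("M%05d", m)
    modules[[mid]] <- list(module_id = mid,
                           name = sprintf("synthetic module %d", m),
                           steps = steps)
  }
  planted <- names(modules)[seq_len(cfg$n_planted_enriched)]
  rows <- list()
  for (gid in gids) {
    in_target <- sim$truth$species[[gid]] %in% target_species
    gene_pool <- sim$genes$gene_id[sim$genes$genome_id == gid]
    acc <- character(0)
    for (mid in names(modules)) {
      complete <- if (mid %in% planted) in_target else
        stats::runif(1) < 0.5
      steps <- modules[[mid]]$steps
      use <- if (complete) seq_along(steps) else
        seq_len(floor(length(steps) / 2))
      acc <- c(acc, vapply(steps[use], function(alts) sample(alts, 1),
                           character(1)))
    }
    rows[[gid]] <- data.frame(
      genome_id = gid,
      gene_id = sample(gene_pool, length(acc), replace = TRUE),
      source = "KEGG", accession = acc,
      description = "synthetic ortholog", stringsAsFactors = FALSE)
  }
  annotations <- do.call(rbind, rows)
  rownames(annotations) <- NULL
  list(annotations = annotations, modules = modules, planted = planted,
       target_species = target_species)
}
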