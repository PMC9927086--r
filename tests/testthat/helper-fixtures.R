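# Shared simulated fixtures, built once per test run (the ANI stage is the
# slow part; memoising keeps the suite inside its budget).
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- simulation_config(seed = 101, n_species = 3,
                             genomes_per_species = 2, genome_len = 9900)
    .fixture_env$cfg <- cfg
    .fixture_env$sim <- simulate_catalog(cfg)
  }
  list(cfg = .fixture_env$cfg, sim = .fixture_env$sim)
}

small_sim_ani <- function() {
  fx <- small_sim()
  if (is.null(.fixture_env$ani)) {
    .fixture_env$ani <- ani_matrix(fx$sim$catalog)
  }
  c(fx, list(ani = .fixture_env$ani))
}

# Manifest mirroring the printed per-site sample counts (672 from the
# methods listing plus the 14 keratinized-gingiva samples of the figures).
hmp_like_manifest <- function() {
  counts <- c(BM = 183, SUPP = 210, SUBP = 19, TD = 220, HP = 1, PT = 19,
              TH = 13, SV = 7, KG = 14)
  do.call(rbind, lapply(names(counts), function(site) {
    data.frame(sample_id = sprintf("%s_%03d", site, seq_len(counts[[site]])),
               oral_site = site,
               total_reads = 1e6L, mapped_reads = 5e4L,
               stringsAsFactors = FALSE)
  }))
}

# Catalog of 113 manifest entries: 11 nonhuman hosts and 2 duplicate
# strains, everything passing quality control.
refseq_like_catalog <- function() {
  lapply(seq_len(113), function(i) {
    toy_genome(sprintf("G%03d", i), strrep("ACGT", 100),
               host = if (i <= 11) "rodent" else "human",
               duplicate_of = if (i %in% c(12, 13)) "G014" else NA_character_,
               completeness = 95, contamination = 1)
  })
}

# ANI table over 100 retained ids engineered so that greedy >98%
# dereplication keeps 74 oral representatives plus 3 nonoral controls.
derep_accounting_fixture <- function() {
  ids <- sprintf("G%03d", 14:113)  # the 100 post-selection genomes
  oral <- ids[1:97]
  nonoral <- ids[98:100]
  reps <- oral[1:74]
  extras <- oral[75:97]
  owner <- rep(reps[1:23], length.out = length(extras))
  catalog <- lapply(ids, function(id) {
    toy_genome(id, strrep("ACGT", 100),
               oral = !(id %in% nonoral),
               completeness = if (id %in% extras) 91 else 95,
               contamination = 1)
  })
  pairs <- t(combn(ids, 2))
  ani <- data.frame(genome_a = pairs[, 1], genome_b = pairs[, 2],
                    ani = 0.90, aligned_fraction = 0.8,
                    stringsAsFactors = FALSE)
  key <- paste(pmin(ani$genome_a, ani$genome_b),
               pmax(ani$genome_a, ani$genome_b))
  for (k in seq_along(extras)) {
    a <- pmin(owner[k], extras[k]); b <- pmax(owner[k], extras[k])
    ani$ani[key == paste(a, b)] <- 0.99
  }
  list(catalog = catalog, ani = ani,
       n_expected = 77, oral = oral, nonoral = nonoral)
}
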