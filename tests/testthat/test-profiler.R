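test_that("coverage accumulates per-base depth with CIGAR semantics", {
  g <- toy_genome("g", strrep("A", 100))
  aln <- data.frame(qname = c("r1", "r2"), flag = 0L,
                    rname = "g_c1", pos = c(1L, 26L),
                    cigar = c("50M", "50M"), stringsAsFactors = FALSE)
  prof <- coverage_from_alignments(aln, list(g), "s1")[["g"]]
  expect_equal(prof$depth[1:25], rep(1L, 25))
  expect_equal(prof$depth[26:50], rep(2L, 25))
  expect_equal(prof$depth[51:75], rep(1L, 25))
  expect_equal(prof$depth[76:100], rep(0L, 25))
  # deletions consume reference without depth; insertions/clips do not
  aln2 <- data.frame(qname = "r", flag = 0L, rname = "g_c1", pos = 11L,
                     cigar = "5M3D5M2I4S", stringsAsFactors = FALSE)
  p2 <- coverage_from_alignments(aln2, list(g))[["g"]]
  expect_equal(which(p2$depth == 1L), c(11:15, 19:23))
  # empty input gives an all-zero profile; unknown contig errors
  p0 <- coverage_from_alignments(aln[0, ], list(g))[["g"]]
  expect_true(all(p0$depth == 0L))
  expect_error(coverage_from_alignments(
    transform(aln, rname = "nope"), list(g)), "nope")
})

test_that("uniform read simulation reaches the Lander-Waterman depth", {
  set.seed(51)
  g <- toy_genome("g", random_dna(10000))
  n_reads <- 1000L; read_len <- 100L
  aln <- data.frame(qname = sprintf("r%04d", 1:n_reads), flag = 0L,
                    rname = "g_c1",
                    pos = sample.int(10000L - read_len + 1L, n_reads,
                                     replace = TRUE),
                    cigar = sprintf("%dM", read_len),
                    stringsAsFactors = FALSE)
  prof <- coverage_from_alignments(aln, list(g))[["g"]]
  expected <- n_reads * read_len / 10000
  se <- sqrt(expected / 10000 * read_len)  # crude depth s.e. bound
  expect_lt(abs(mean(prof$depth) - expected), 3 * max(se, 0.5))
})

test_that("breadth and genome detection honor the inclusive 50% rule", {
  expect_equal(breadth(profile_from_depth(rep(0, 10))), 0)
  expect_equal(breadth(profile_from_depth(c(rep(0, 5), rep(3, 5)))), 0.5)
  set.seed(52)
  d <- rpois(1000, 0.8)
  expect_equal(breadth(profile_from_depth(d)), sum(d >= 1) / 1000)
  expect_true(detect_genome(profile_from_depth(c(rep(0, 500), rep(1, 500)))))
  expect_false(detect_genome(profile_from_depth(c(rep(0, 501), rep(1, 499)))))
})

test_that("gene detection applies the inclusive 90% rule on gene positions", {
  depth <- c(rep(1, 90), rep(0, 10), rep(5, 100))
  prof <- profile_from_depth(depth)
  gene90 <- data.frame(gene_id = "x", contig_id = "g_c1",
                       start = 1L, stop = 100L)
  expect_true(detect_gene(prof, gene90))
  prof89 <- profile_from_depth(c(rep(1, 89), rep(0, 11), rep(5, 100)))
  gene89 <- data.frame(gene_id = "y", contig_id = "g_c1",
                       start = 1L, stop = 100L)
  expect_false(detect_gene(prof89, gene89))
  oob <- data.frame(gene_id = "z", contig_id = "g_c1",
                    start = 150L, stop = 250L)
  expect_error(detect_gene(prof, oob), "bounds")
})

test_that("interquartile mean depth matches the sort-and-slice definition", {
  expect_equal(q2q3_mean(profile_from_depth(rep(7, 8))), 7)
  expect_equal(q2q3_mean(profile_from_depth(c(0, 0, 1, 1, 2, 2, 9, 9))), 1.5)
  expect_equal(q2q3_mean(profile_from_depth(rep(0, 20))), 0)
  expect_error(q2q3_mean(profile_from_depth(c(1, 2, 3))), ">= 4")
  set.seed(53)
  for (L in c(8, 9, 10, 11, 101, 1000)) {
    d <- rpois(L, 3)
    s <- sort(d)
    oracle <- mean(s[(floor(L / 4) + 1):ceiling(3 * L / 4)])
    expect_equal(q2q3_mean(profile_from_depth(d)), oracle)
    # invariant to permutation of positions
    expect_equal(q2q3_mean(profile_from_depth(sample(d))), oracle)
    # bounded by the depth range
    expect_gte(oracle, min(d)); expect_lte(oracle, max(d))
  }
})

test_that("relative abundance normalises within a sample", {
  p1 <- profile_from_depth(rep(3, 100), "gA")
  p2 <- profile_from_depth(rep(1, 100), "gB")
  tab <- relative_abundance(list(gA = p1, gB = p2))
  expect_equal(tab$rel_abundance, c(0.75, 0.25))
  expect_equal(sum(tab$rel_abundance), 1, tolerance = 1e-9)
  solo <- relative_abundance(list(gA = p1))
  expect_equal(solo$rel_abundance, 1.0)
  # all-zero sample: flagged, abundances zero
  zero <- relative_abundance(list(gA = profile_from_depth(rep(0, 100), "gA")))
  expect_true(all(zero$flagged))
  expect_equal(zero$rel_abundance, 0)
  # undetected genomes still count toward the default denominator
  p3 <- profile_from_depth(c(rep(0, 60), rep(2, 40)), "gC")  # breadth 0.4
  tab3 <- relative_abundance(list(gA = p1, gC = p3))
  expect_false(tab3$detected[tab3$genome_id == "gC"])
  expect_gt(tab3$rel_abundance[tab3$genome_id == "gC"], 0)
  # 'detected' denominator excludes them instead
  tab4 <- relative_abundance(list(gA = p1, gC = p3),
                             denominator = "detected")
  expect_equal(tab4$rel_abundance[tab4$genome_id == "gA"], 1)
  expect_equal(tab4$rel_abundance[tab4$genome_id == "gC"], 0)
})

test_that("planted abundance ratios are recovered within 5% relative error", {
  cfg <- simulation_config(seed = 54, n_species = 4,
                           genomes_per_species = 1, genome_len = 9900,
                           n_sites = 1, depth_per_site = 50,
                           tropism = list(S1 = 1L, S2 = 1L, S3 = 1L, S4 = 1L))
  sim <- simulate_catalog(cfg)
  w <- matrix(c(8, 4, 2, 1) / 8, ncol = 1,
              dimnames = list(names(sim$catalog), "SUPP"))
  mg <- simulate_metagenomes(cfg, sim, samples_per_site = 1, weights = w)
  profs <- coverage_from_alignments(mg$samples[[1]], sim$catalog, "s")
  tab <- relative_abundance(profs)
  got <- tab$rel_abundance / max(tab$rel_abundance) * 8
  expect_equal(got, c(8, 4, 2, 1), tolerance = 0.05)
})

test_that("species roll-up sums members and keeps only samples with a detection", {
  tab <- data.frame(
    sample_id = rep(c("s1", "s2"), each = 3),
    genome_id = rep(c("g1", "g2", "g3"), 2),
    detected = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    q2q3_mean = 1,
    rel_abundance = c(0.2, 0.3, 0.1, 0.5, 0.4, 0.1),
    flagged = FALSE, stringsAsFactors = FALSE)
  map <- c(g1 = "spA", g2 = "spA", g3 = "spB")
  out <- species_rollup(tab, map)
  expect_equal(unique(out$sample_id), "s1")  # s2 had no detections
  expect_equal(out$rel_abundance[out$species == "spA"], 0.5)
  expect_equal(out$rel_abundance[out$species == "spB"], 0.1)
  expect_error(species_rollup(tab, map[1:2]), "g3")
})

test_that("SAM round trip preserves the alignment table", {
  aln <- data.frame(qname = c("r1", "r2"), flag = 0L,
                    rname = c("c1", "c2"), pos = c(5L, 10L),
                    cigar = c("100M", "50M2D48M"), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, c(c1 = 1000L, c2 = 2000L), path)
  back <- read_sam(path)
  expect_equal(back[, c("qname", "rname", "pos", "cigar")],
               aln[, c("qname", "rname", "pos", "cigar")])
  # unmapped and header lines are skipped
  writeLines(c("@HD\tVN:1.6", "u\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), path)
  expect_equal(nrow(read_sam(path)), 0)
})

test_that("detection is monotone: adding alignments never un-detects", {
  set.seed(55)
  g <- toy_genome("g", random_dna(2000))
  base <- data.frame(qname = sprintf("r%03d", 1:15), flag = 0L,
                     rname = "g_c1",
                     pos = sample.int(1901L, 15, replace = TRUE),
                     cigar = "100M", stringsAsFactors = FALSE)
  extra <- transform(base, qname = paste0(qname, "b"),
                     pos = sample.int(1901L, 15, replace = TRUE))
  p1 <- coverage_from_alignments(base, list(g))[["g"]]
  p2 <- coverage_from_alignments(rbind(base, extra), list(g))[["g"]]
  expect_true(all(p2$depth >= p1$depth))
  if (detect_genome(p1)) expect_true(detect_genome(p2))
  gene <- data.frame(gene_id = "x", contig_id = "g_c1",
                     start = 100L, stop = 400L)
  if (detect_gene(p1, gene)) expect_true(detect_gene(p2, gene))
})
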