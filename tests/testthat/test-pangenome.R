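test_that("minbit follows its definition and matches brute-force alignment", {
  set.seed(21)
  p <- random_protein(50)
  edges <- pairwise_scores(gene_calls(
    gene_id = c("a", "b"), genome_id = c("g1", "g2"),
    contig_id = "c", start = 1, stop = 151, protein = c(p, p)))
  cross <- edges[edges$gene_a != edges$gene_b, ]
  expect_equal(cross$minbit, 1.0, tolerance = 1e-9)

  # unrelated proteins fall under the 0.5 criterion
  q <- random_protein(50)
  e2 <- pairwise_scores(gene_calls(
    gene_id = c("a", "b"), genome_id = c("g1", "g2"),
    contig_id = "c", start = 1, stop = 151, protein = c(p, q)),
    seed_k = 0)
  cross2 <- e2[e2$gene_a != e2$gene_b, ]
  expect_true(nrow(cross2) == 0 || all(cross2$minbit < 0.5))

  # toy six-gene family set: retained edges equal the brute-force oracle
  set.seed(22)
  fam1 <- random_protein(60)
  fam2 <- random_protein(60)
  prots <- c(a1 = fam1, a2 = mutate_protein(fam1, 5),
             a3 = mutate_protein(fam1, 8),
             b1 = fam2, b2 = mutate_protein(fam2, 6),
             b3 = mutate_protein(fam2, 10))
  genes <- gene_calls(gene_id = names(prots),
                      genome_id = paste0("g", 1:6), contig_id = "c",
                      start = 1, stop = 181, protein = unname(prots))
  for (k in c(0L, 4L)) {
    edges <- minbit_filter(pairwise_scores(genes, seed_k = k))
    oracle <- minbit_oracle(prots)
    keep <- oracle[oracle$minbit >= 0.5, ]
    got <- paste(pmin(edges$gene_a, edges$gene_b),
                 pmax(edges$gene_a, edges$gene_b))
    want <- paste(pmin(keep$gene_a, keep$gene_b),
                  pmax(keep$gene_a, keep$gene_b))
    expect_setequal(got, want)
    # minbit values agree with the oracle (bitscore scaling cancels in the
    # ratio only approximately because of the ln K offset; compare raw)
    m <- match(got, want)
    expect_true(all(abs(sort(edges$minbit) - sort(keep$minbit)) < 0.05))
  }
})

test_that("minbit filtering keeps the inclusive boundary and drops self-edges", {
  edges <- data.frame(gene_a = c("a", "b", "c", "a", "b", "c"),
                      gene_b = c("a", "b", "c", "b", "c", "a"),
                      score = 1, minbit = c(1, 1, 1, 0.49, 0.50, 0.90))
  out <- minbit_filter(edges)
  expect_equal(sort(out$minbit), c(0.50, 0.90))
  expect_false(any(out$gene_a == out$gene_b))
  empty <- edges[0, ]
  expect_equal(nrow(minbit_filter(empty)), 0)
  expect_error(minbit_filter(edges[4:6, ]), "self-score")
})

test_that("minbit is symmetric and bounded", {
  set.seed(23)
  prots <- c(x = random_protein(40), y = mutate_protein(random_protein(40), 3))
  genes <- gene_calls(gene_id = names(prots), genome_id = c("g1", "g2"),
                      contig_id = "c", start = 1, stop = 121,
                      protein = unname(prots))
  edges <- pairwise_scores(genes, seed_k = 0)
  cross <- edges[edges$gene_a != edges$gene_b, ]
  expect_true(all(cross$minbit <= 1 + 1e-9))
})

test_that("MCL separates disconnected cliques and isolates singletons", {
  clique <- function(ids) {
    p <- t(combn(ids, 2))
    data.frame(gene_a = p[, 1], gene_b = p[, 2], minbit = 0.9,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(clique(c("a1", "a2", "a3")), clique(c("b1", "b2", "b3")))
  memb <- mcl_cluster(edges, c("a1", "a2", "a3", "b1", "b2", "b3", "lone"))
  expect_equal(length(unique(memb)), 3)
  expect_equal(length(unique(memb[c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(memb[c("b1", "b2", "b3")])), 1)
  expect_false(memb[["lone"]] %in% memb[c("a1", "b1")])
  expect_error(mcl_cluster(transform(edges, minbit = c(Inf, rep(0.9, 5))),
                           unique(c(edges$gene_a, edges$gene_b))), "finite")
})

test_that("MCL at inflation 10 splits weakly bridged families like the oracles", {
  fam <- function(pre) paste0(pre, 1:4)
  clique_edges <- function(ids, w) {
    p <- t(combn(ids, 2))
    data.frame(gene_a = p[, 1], gene_b = p[, 2], minbit = w,
               stringsAsFactors = FALSE)
  }
  genes <- c(fam("a"), fam("b"), fam("c"))
  edges <- rbind(clique_edges(fam("a"), 0.9), clique_edges(fam("b"), 0.9),
                 clique_edges(fam("c"), 0.9),
                 data.frame(gene_a = c("a1", "b1"), gene_b = c("b2", "c2"),
                            minbit = 0.55))
  memb <- mcl_cluster(edges, genes, inflation = 10)
  expect_equal(length(unique(memb)), 3)
  for (f in list(fam("a"), fam("b"), fam("c"))) {
    expect_equal(length(unique(memb[f])), 1)
  }
  # bridge-removal connected-components oracle
  strong <- edges[edges$minbit > 0.6, ]
  g <- unique(c(edges$gene_a, edges$gene_b))
  adj <- matrix(0, length(g), length(g), dimnames = list(g, g))
  adj[cbind(strong$gene_a, strong$gene_b)] <- 1
  adj <- adj + t(adj)
  cc <- mcl_oracle((adj > 0) * 0.9, inflation = 2)  # components of cliques
  expect_equal(length(unique(cc)), 3)
  # independent textbook MCL implementation on the full weighted graph
  adj2 <- matrix(0, length(g), length(g), dimnames = list(g, g))
  adj2[cbind(edges$gene_a, edges$gene_b)] <- edges$minbit
  adj2 <- pmax(adj2, t(adj2))
  oracle <- mcl_oracle(adj2, inflation = 10)
  expect_equal(length(unique(oracle)), 3)
  split_by <- function(m) unname(split(names(m), m))
  expect_setequal(lapply(split_by(memb), sort), lapply(split_by(oracle), sort))
})

test_that("mean MCL cluster size is non-increasing in inflation", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 18
    ids <- sprintf("n%02d", seq_len(n))
    p <- t(combn(ids, 2))
    w <- runif(nrow(p))
    keep <- w > 0.55
    edges <- data.frame(gene_a = p[keep, 1], gene_b = p[keep, 2],
                        minbit = w[keep], stringsAsFactors = FALSE)
    sizes <- vapply(c(2, 5, 10), function(infl) {
      m <- mcl_cluster(edges, ids, inflation = infl)
      mean(table(m))
    }, numeric(1))
    expect_true(all(diff(sizes) <= 1e-9))
  }
})

test_that("gene conservation: every gene lands in exactly one cluster", {
  fx <- small_sim()
  edges <- minbit_filter(pairwise_scores(fx$sim$genes))
  memb <- mcl_cluster(edges, fx$sim$genes$gene_id)
  expect_setequal(names(memb), fx$sim$genes$gene_id)
  mat <- pangenome_matrix(memb, fx$sim$genes)
  expect_equal(sum(mat), nrow(fx$sim$genes))
  cls <- classify_clusters(mat)
  expect_equal(cls$core + cls$accessory + cls$singleton, cls$total)
  # planted gene families are recovered as clusters
  fam <- fx$sim$truth$gene_family[names(memb)]
  agree <- vapply(split(memb, fam), function(v) length(unique(v)) == 1,
                  logical(1))
  expect_gt(mean(agree), 0.95)
})

test_that("cluster classification matches hand-counted occupancy", {
  mat <- matrix(c(1, 1, 1,   # core
                  2, 0, 0,   # singleton
                  0, 1, 1,   # accessory
                  1, 0, 1,   # accessory
                  0, 0, 3),  # singleton
                nrow = 3, ncol = 5,
                dimnames = list(c("g1", "g2", "g3"), paste0("c", 1:5)))
  cls <- classify_clusters(mat)
  expect_equal(unname(c(cls$core, cls$accessory, cls$singleton, cls$total)),
               c(1, 2, 2, 5))
  expect_equal(as.character(cls$category),
               c("core", "singleton", "accessory", "accessory", "singleton"))
})

test_that("Ward dendrogram matches the Lance-Williams oracle and recovers clades", {
  # identical genomes merge at height zero
  two <- matrix(c(1, 2, 0, 1, 2, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  hc <- genome_dendrogram(two)$hclust
  expect_equal(hc$height, 0)
  expect_error(genome_dendrogram(two[1, , drop = FALSE]), "at least 2")

  set.seed(33)
  X <- matrix(rpois(6 * 20, 2), nrow = 6,
              dimnames = list(paste0("g", 1:6), NULL))
  hc2 <- genome_dendrogram(X)$hclust
  expect_equal(sort(hc2$height), sort(ward_heights_oracle(X)),
               tolerance = 1e-8)

  # planted three-clade frequency matrix: cutting at 3 recovers the clades
  base <- matrix(rpois(3 * 40, 1), nrow = 3)
  M <- base[rep(1:3, each = 3), ] + matrix(rbinom(9 * 40, 1, 0.05), nrow = 9)
  rownames(M) <- sprintf("s%d_g%d", rep(1:3, each = 3), rep(1:3, 3))
  ct <- stats::cutree(genome_dendrogram(M)$hclust, k = 3)
  expect_equal(length(unique(paste(ct, rep(1:3, each = 3)))), 3)
})
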