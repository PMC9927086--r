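test_that("single-copy core extraction follows the occupancy rules", {
  mat <- matrix(c(1, 1, 1, 1,   # universal single copy
                  1, 2, 1, 1,   # duplicated in one genome -> excluded
                  1, 1, 0, 1,   # missing in one genome -> excluded
                  1, 1, 1, 1),
                nrow = 4,
                dimnames = list(paste0("g", 1:4), paste0("c", 1:4)))
  scg <- extract_scg(mat)
  expect_setequal(scg$clusters, c("c1", "c4"))
  expect_equal(scg$n_genes, 8)
  # brute-force occupancy scan agrees
  brute <- colnames(mat)[apply(mat, 2, function(col) all(col == 1))]
  expect_setequal(scg$clusters, brute)
  # planted 77-genome accounting: 496 universal single-copy clusters
  big <- cbind(
    matrix(1L, nrow = 77, ncol = 496),
    matrix(rbinom(77 * 40, 1, 0.4), nrow = 77),
    matrix(2L, nrow = 77, ncol = 3))
  colnames(big) <- sprintf("GC_%04d", seq_len(ncol(big)))
  rownames(big) <- sprintf("g%02d", 1:77)
  scg77 <- extract_scg(big)
  expect_gte(length(scg77$clusters), 496)
  expect_equal(sum(big[, scg77$clusters]), scg77$n_genes)
  planted_only <- extract_scg(big[, 1:496])
  expect_equal(planted_only$n_genes, 38192)
})

test_that("center-star alignment degenerates to pairwise NW and is lossless", {
  expect_error(align_cluster(character(0)), "empty")
  same <- c(g1 = "MKVLA", g2 = "MKVLA", g3 = "MKVLA")
  expect_identical(unname(align_cluster(same)), unname(same))

  set.seed(41)
  a <- random_protein(40)
  b <- mutate_protein(a, 4)
  out <- align_cluster(c(x = a, y = b))
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = get("BLOSUM62", envir = e),
    gapOpening = 11, gapExtension = 1)
  expect_setequal(unname(out),
                  c(as.character(Biostrings::alignedPattern(aln)),
                    as.character(Biostrings::alignedSubject(aln))))

  # one member with an internal 3-residue deletion: gap block of width 3
  set.seed(42)
  base <- random_protein(50)
  del <- paste0(substr(base, 1, 24), substr(base, 28, 50))
  members <- c(m1 = base, m2 = mutate_protein(base, 2),
               m3 = mutate_protein(base, 3), m4 = mutate_protein(base, 1),
               m5 = del)
  out5 <- align_cluster(members)
  expect_equal(length(unique(nchar(out5))), 1)
  for (nm in names(members)) {
    expect_equal(gsub("-", "", out5[[nm]]), members[[nm]])
  }
  expect_equal(sum(strsplit(out5[["m5"]], "")[[1]] == "-"), 3)
  # the 3 gaps are contiguous
  expect_match(out5[["m5"]], "^[^-]+---[^-]+$")
})

test_that("concatenation trims columns by the strict 50% gap rule", {
  aln1 <- c(t1 = "AC-A", t2 = "AC-A", t3 = "ACCA", t4 = "ACCA")  # col3: 50% gaps
  aln2 <- c(t1 = "-A", t2 = "-A", t3 = "-A", t4 = "GA")          # col1: 75%
  sm <- concatenate_and_trim(list(c1 = aln1, c2 = aln2))
  expect_equal(unname(nchar(sm$rows)), rep(5, 4))   # 4 kept + 1 kept
  expect_equal(sm$partition_map$start, c(1, 5))
  expect_equal(sm$partition_map$end, c(4, 5))
  # brute-force column scan oracle
  full <- cbind(do.call(rbind, strsplit(aln1[sort(names(aln1))], "")),
                do.call(rbind, strsplit(aln2[sort(names(aln2))], "")))
  keep <- colMeans(full == "-") <= 0.5
  expect_equal(unname(sm$rows["t1"]),
               paste(full["t1", keep], collapse = ""))
  # all-gap columns always removed
  sm2 <- concatenate_and_trim(list(c = c(a = "A--B", b = "C--D")))
  expect_equal(unname(sm2$rows), c("AB", "CD"))
  # trimming is idempotent
  rows_as_aln <- list(c = sm$rows)
  expect_equal(concatenate_and_trim(rows_as_aln)$rows, sm$rows)
  # taxa mismatch errors with the offending cluster named
  expect_error(concatenate_and_trim(list(ok = aln1, bad = aln2[1:3])), "bad")
})

test_that("neighbor joining recovers additive and simulated topologies", {
  expect_error(build_tree(list(taxa = c("a", "b"),
                               rows = c(a = "A", b = "A"))), "3 taxa")
  # sequences simulated on a known 8-taxon tree (pure birth, WAG-free
  # Poisson substitutions): NJ on WAG distances recovers the topology
  set.seed(43)
  tree <- ape::rtree(8, br = NULL)
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.05, 0.25)
  aas <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
           "S","T","V","W","Y")
  L <- 400
  root_seq <- sample(aas, L, replace = TRUE)
  seqs <- list()
  evolve <- function(node, seq) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    for (k in seq_along(kids)) {
      child <- kids[k]
      bl <- tree$edge.length[which(tree$edge[, 1] == node &
                                     tree$edge[, 2] == child)]
      s <- seq
      n_sub <- rpois(1, bl * L)
      if (n_sub > 0) {
        idx <- sample(L, min(n_sub, L))
        s[idx] <- vapply(s[idx], function(x) sample(setdiff(aas, x), 1),
                         character(1))
      }
      if (child <= length(tree$tip.label)) {
        seqs[[tree$tip.label[child]]] <<- paste(s, collapse = "")
      } else evolve(child, s)
    }
  }
  evolve(length(tree$tip.label) + 1L, root_seq)
  sm <- list(taxa = names(seqs),
             rows = unlist(seqs))
  est <- build_tree(sm)
  expect_equal(compare_trees(est, tree)$rf, 0)
  expect_true(all(est$edge.length >= 0))
  # two identical rows form a zero-length cherry
  sm2 <- sm
  sm2$rows["t1"] <- sm2$rows["t2"]
  est2 <- build_tree(sm2)
  m <- ape::cophenetic.phylo(est2)
  expect_equal(unname(m["t1", "t2"]), 0, tolerance = 1e-9)
})

test_that("Robinson-Foulds distance matches bipartition enumeration", {
  set.seed(44)
  t1 <- ape::rtree(6)
  expect_equal(compare_trees(t1, t1)$rf, 0)
  # one NNI away on 5 taxa: RF = 2
  a <- ape::read.tree(text = "(((A,B),C),D,E);")
  b <- ape::read.tree(text = "(((A,B),D),C,E);")
  expect_equal(compare_trees(a, b)$rf, 2)
  # caterpillar vs balanced 6-taxon trees, cross-checked against phangorn
  cat6 <- ape::read.tree(text = "(((((A,B),C),D),E),F);")
  bal6 <- ape::read.tree(text = "(((A,B),(C,D)),(E,F));")
  got <- compare_trees(cat6, bal6)$rf
  expect_equal(got, as.numeric(phangorn::RF.dist(ape::unroot(cat6),
                                                 ape::unroot(bal6))))
  # leaf-set mismatch reports the symmetric difference
  t2 <- ape::rtree(6)
  t2$tip.label[1] <- "zzz"
  expect_error(compare_trees(t1, t2), "zzz")
  # pairing table covers every leaf once
  cmp <- compare_trees(cat6, bal6)
  expect_setequal(cmp$pairing$leaf, cat6$tip.label)
  expect_false(any(duplicated(cmp$pairing$pos_a)))
})
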