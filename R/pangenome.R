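#' Construct a gene-call table
#'
#' @param gene_id,genome_id,contig_id Character vectors.
#' @param start,stop 1-based inclusive nucleotide coordinates, start < stop.
#' @param strand "+" or "-".
#' @param protein Amino-acid sequences (uppercase; X allowed, scored 0).
#' @return data.frame of gene calls.
#' @export
gene_calls <- function(gene_id, genome_id, contig_id, start, stop,
                       strand = "+", protein) {
  stopifnot(all(start < stop), all(nzchar(protein)),
            !anyDuplicated(gene_id))
  data.frame(gene_id = gene_id, genome_id = genome_id,
             contig_id = contig_id, start = as.integer(start),
             stop = as.integer(stop), strand = strand,
             protein = toupper(protein), stringsAsFactors = FALSE)
}

# Karlin-Altschul bitscore with gapped BLOSUM62 constants. Only ratios of
# scores enter minbit, so the raw score is an equivalent fallback; both are
# exposed and give identical filtering.
.bitscore <- function(raw, lambda = 0.267, K = 0.041) {
  (lambda * raw - log(K)) / log(2)
}

# k-mer seed index for the BLAST-like prefilter: which proteins share at
# least min_shared k-mers with a query.
.kmer_sets <- function(proteins, k) {
  lapply(proteins, function(p) {
    n <- nchar(p)
    if (n < k) return(character(0))
    unique(substring(p, 1:(n - k + 1), k:n))
  })
}

#' All-vs-all protein similarity edges
#'
#' Smith-Waterman local alignment (BLOSUM62, gap open 11 / extend 1) over
#' every protein pair, reported as Karlin-Altschul bitscores together with
#' the minbit normalisation: cross-score divided by the smaller of the two
#' self-scores. Self-edges are included (they carry the self-scores used by
#' the normalisation); cross edges with raw score <= 0 are dropped. A
#' shared-k-mer seed prefilter (default: at least one shared 4-mer) skips
#' alignment of clearly unrelated pairs; set \code{seed_k = 0} to disable.
#'
#' @param genes Gene-call data.frame (see \code{\link{gene_calls}}).
#' @param seed_k k-mer size of the seed prefilter (0 disables).
#' @param min_shared_kmers Minimum shared k-mers required to align a pair.
#' @return data.frame: gene_a, gene_b, score (bitscore), minbit; includes
#'   one self row per gene (gene_a == gene_b, minbit 1).
#' @export
pairwise_scores <- function(genes, seed_k = 4L, min_shared_kmers = 1L) {
  if (any(!nzchar(genes$protein))) {
    stop("empty protein sequence for gene(s): ",
         paste(genes$gene_id[!nzchar(genes$protein)], collapse = ", "))
  }
  prots <- genes$protein
  ids <- genes$gene_id
  n <- length(prots)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  submat <- get("BLOSUM62", envir = environment())
  aaset <- Biostrings::AAStringSet(prots)
  self_raw <- vapply(seq_len(n), function(i) {
    Biostrings::pairwiseAlignment(aaset[i], aaset[[i]], type = "local",
                                  substitutionMatrix = submat,
                                  gapOpening = 11, gapExtension = 1,
                                  scoreOnly = TRUE)
  }, numeric(1))
  kmers <- if (seed_k > 0) .kmer_sets(prots, seed_k) else NULL
  rows_a <- character(0); rows_b <- character(0); raw <- numeric(0)
  for (i in seq_len(n)) {
    if (i == n) break
    js <- seq.int(i + 1, n)
    if (!is.null(kmers)) {
      shared <- vapply(js, function(j) {
        sum(kmers[[i]] %in% kmers[[j]])
      }, numeric(1))
      js <- js[shared >= min_shared_kmers]
    }
    if (length(js) == 0) next
    sc <- Biostrings::pairwiseAlignment(
      aaset[js], aaset[[i]], type = "local",
      substitutionMatrix = submat, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    keep <- sc > 0
    rows_a <- c(rows_a, rep(ids[i], sum(keep)))
    rows_b <- c(rows_b, ids[js][keep])
    raw <- c(raw, sc[keep])
  }
  self_bit <- .bitscore(self_raw)
  edges <- data.frame(
    gene_a = c(ids, rows_a), gene_b = c(ids, rows_b),
    score = c(self_bit, .bitscore(raw)), stringsAsFactors = FALSE)
  sa <- stats::setNames(self_bit, ids)
  edges$minbit <- edges$score / pmin(sa[edges$gene_a], sa[edges$gene_b])
  rownames(edges) <- NULL
  edges
}

#' Filter a similarity graph by the minbit criterion
#'
#' Keeps cross edges with minbit >= \code{threshold} (boundary inclusive)
#' and removes self-edges from the output graph.
#'
#' @param edges Edge data.frame from \code{\link{pairwise_scores}}.
#' @param threshold Minbit threshold, default 0.5.
#' @return Filtered edge data.frame (gene_a, gene_b, score, minbit).
#' @export
minbit_filter <- function(edges, threshold = 0.5) {
  if (nrow(edges) == 0) return(edges)
  selfs <- edges$gene_a == edges$gene_b
  genes <- unique(c(edges$gene_a, edges$gene_b))
  have_self <- genes %in% edges$gene_a[selfs]
  if (!all(have_self)) {
    stop("missing self-score for gene(s): ",
         paste(genes[!have_self], collapse = ", "))
  }
  out <- edges[!selfs & edges$minbit >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Markov clustering of a gene similarity graph
#'
#' Dense MCL on the minbit-weighted undirected graph: self-loops of weight
#' equal to each node's maximum incident weight (1 for isolated nodes) are
#' added, columns are made stochastic, and expansion (matrix square) is
#' alternated with element-wise inflation until the matrix changes by less
#' than \code{tol} or \code{max_iter} rounds elapse. Entries below
#' \code{prune} are zeroed each round. Clusters are read off attractor rows;
#' overlapping attractor supports are merged and any residual ambiguity is
#' resolved toward the lowest gene_id, so the result is deterministic for a
#' fixed input order.
#'
#' @param edges Filtered edge data.frame (gene_a, gene_b, minbit).
#' @param genes Character vector of all gene ids (so genes with no
#'   surviving edges still receive singleton clusters).
#' @param inflation Inflation exponent, default 10.
#' @param prune Entries below this are zeroed, default 1e-8.
#' @param tol Convergence tolerance on the max entry change, default 1e-6.
#' @param max_iter Iteration cap, default 200.
#' @return Named integer vector: cluster label per gene id.
#' @export
mcl_cluster <- function(edges, genes, inflation = 10, prune = 1e-8,
                        tol = 1e-6, max_iter = 200L) {
  genes <- sort(unique(genes))
  n <- length(genes)
  M <- matrix(0, n, n, dimnames = list(genes, genes))
  if (nrow(edges) > 0) {
    w <- edges$minbit
    if (any(!is.finite(w)) || any(w < 0)) {
      stop("edge weights must be finite and non-negative")
    }
    ia <- match(edges$gene_a, genes)
    ib <- match(edges$gene_b, genes)
    for (k in seq_along(w)) {
      M[ia[k], ib[k]] <- max(M[ia[k], ib[k]], w[k])
      M[ib[k], ia[k]] <- max(M[ib[k], ia[k]], w[k])
    }
  }
  loop <- apply(M, 1, max)
  diag(M) <- ifelse(loop > 0, loop, 1)
  normalize <- function(M) {
    cs <- colSums(M)
    dead <- cs == 0
    if (any(dead)) {     # fully pruned column: restart as its own attractor
      M[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    sweep(M, 2, cs, "/")
  }
  M <- normalize(M)
  for (iter in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  # attractors: nodes retaining positive mass on their own row
  attract <- which(diag(M) > 0)
  membership <- rep(NA_integer_, n)
  cluster_of_attr <- rep(NA_integer_, length(attract))
  next_label <- 0L
  for (ai in seq_along(attract)) {
    if (!is.na(cluster_of_attr[ai])) next
    next_label <- next_label + 1L
    support <- M[attract[ai], ] > 0
    # merge attractors whose supports overlap (transitively)
    repeat {
      overlapping <- vapply(seq_along(attract), function(bi) {
        is.na(cluster_of_attr[bi]) && any(M[attract[bi], ] > 0 & support)
      }, logical(1))
      if (!any(overlapping)) break
      for (bi in which(overlapping)) {
        cluster_of_attr[bi] <- next_label
        support <- support | (M[attract[bi], ] > 0)
      }
    }
    membership[support & is.na(membership)] <- next_label
  }
  # genes with no attractor mass (numerically orphaned): own clusters
  for (i in which(is.na(membership))) {
    next_label <- next_label + 1L
    membership[i] <- next_label
  }
  stats::setNames(membership, genes)
}

#' Build the per-genome gene-cluster frequency matrix
#'
#' @param membership Named cluster labels from \code{\link{mcl_cluster}}.
#' @param genes Gene-call data.frame (maps gene_id to genome_id).
#' @return Integer matrix, genomes x clusters, entries = copy counts.
#'   Cluster columns are named GC_0001, ... in order of first appearance by
#'   lowest member gene_id.
#' @export
pangenome_matrix <- function(membership, genes) {
  genome_of <- stats::setNames(genes$genome_id, genes$gene_id)
  gid <- names(membership)
  stopifnot(all(gid %in% names(genome_of)))
  # stable cluster naming: order clusters by their smallest gene_id
  first_gene <- tapply(gid, membership, min)
  ord <- order(first_gene)
  relabel <- stats::setNames(seq_along(ord), names(first_gene)[ord])
  cl <- relabel[as.character(membership)]
  cl_names <- sprintf("GC_%04d", seq_along(ord))
  genomes <- sort(unique(genes$genome_id))
  mat <- matrix(0L, length(genomes), length(ord),
                dimnames = list(genomes, cl_names))
  for (k in seq_along(gid)) {
    g <- genome_of[[gid[k]]]
    mat[g, cl[k]] <- mat[g, cl[k]] + 1L
  }
  attr(mat, "members") <- split(gid, cl_names[cl])
  mat
}

#' Partition gene clusters into core, accessory and singleton classes
#'
#' Core clusters occur in every genome, singletons in exactly one, and
#' accessory clusters in more than one but not all; the three classes
#' partition the pangenome.
#'
#' @param matrix Genomes x clusters copy-count matrix.
#' @return List: per-cluster \code{category} factor plus the counts
#'   \code{core}, \code{accessory}, \code{singleton}, \code{total}.
#' @export
classify_clusters <- function(matrix) {
  stopifnot(nrow(matrix) >= 1, ncol(matrix) >= 1)
  occ <- colSums(matrix > 0)
  category <- factor(ifelse(occ == nrow(matrix), "core",
                     ifelse(occ == 1, "singleton", "accessory")),
                     levels = c("core", "accessory", "singleton"))
  names(category) <- colnames(matrix)
  counts <- table(category)
  list(category = category,
       core = unname(counts["core"]),
       accessory = unname(counts["accessory"]),
       singleton = unname(counts["singleton"]),
       total = ncol(matrix))
}

#' Hierarchical genome dendrogram on gene-cluster frequencies
#'
#' Euclidean distance over the cluster-frequency rows with Ward linkage
#' (\code{ward.D2}, the squared-distance Ward criterion).
#'
#' @param matrix Genomes x clusters copy-count matrix (>= 2 genomes).
#' @return List: \code{hclust} (the merge tree) and \code{newick} (the same
#'   tree serialised via \pkg{ape}).
#' @export
genome_dendrogram <- function(matrix) {
  if (nrow(matrix) < 2) stop("need at least 2 genomes for a dendrogram")
  hc <- stats::hclust(stats::dist(matrix, method = "euclidean"),
                      method = "ward.D2")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, newick = ape::write.tree(phy))
}
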