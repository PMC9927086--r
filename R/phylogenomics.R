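#' Select single-copy core gene clusters
#'
#' A cluster qualifies when it occurs in all \code{n_genomes} genomes with
#' exactly one member per genome; concatenating such clusters yields the
#' phylogenomic supermatrix.
#'
#' @param matrix Genomes x clusters copy-count matrix.
#' @param n_genomes Number of genomes a cluster must cover (defaults to all
#'   rows of \code{matrix}).
#' @return List: \code{clusters} (qualifying cluster ids), \code{n_genes}
#'   (= length(clusters) * n_genomes).
#' @export
extract_scg <- function(matrix, n_genomes = nrow(matrix)) {
  single <- colSums(matrix == 1L) == n_genomes &
    colSums(matrix > 0L) == n_genomes
  clusters <- colnames(matrix)[single]
  list(clusters = clusters, n_genes = length(clusters) * n_genomes)
}

# Global Needleman-Wunsch of two proteins returning the two aligned rows.
.nw_pair <- function(a, b, submat) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = submat, gapOpening = 11, gapExtension = 1)
  c(as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)))
}

#' Center-star multiple alignment of a gene cluster
#'
#' The center sequence is the member with the maximum summed global
#' alignment score against all others (BLOSUM62, gap open 11 / extend 1);
#' every other member is aligned to the center pairwise and the pairwise
#' alignments are merged by taking, at each center position, the maximum
#' insertion length observed across members. Ungapping any output row
#' returns its input sequence.
#'
#' @param members Named character vector of protein sequences (>= 1).
#' @return Named character vector of equal-length aligned rows (gap "-").
#' @export
align_cluster <- function(members) {
  if (length(members) == 0) stop("cannot align an empty member list")
  if (length(members) == 1) return(members)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  submat <- get("BLOSUM62", envir = environment())
  n <- length(members)
  score <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(members[seq.int(i + 1, n)]),
      Biostrings::AAString(members[[i]]), type = "global",
      substitutionMatrix = submat, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    score[i, seq.int(i + 1, n)] <- sc
    score[seq.int(i + 1, n), i] <- sc
  }
  center <- which.max(rowSums(score))
  cen_seq <- members[[center]]
  Lc <- nchar(cen_seq)
  others <- setdiff(seq_len(n), center)
  # ins[[j]][i+1] = gaps inserted before center position i (i = 0..Lc)
  aligned <- vector("list", n)
  ins <- matrix(0L, length(others), Lc + 1L)
  pair_rows <- vector("list", length(others))
  for (k in seq_along(others)) {
    rows <- .nw_pair(cen_seq, members[[others[k]]], submat)
    pair_rows[[k]] <- rows
    cpos <- 0L
    run <- 0L
    for (ch in strsplit(rows[1], "")[[1]]) {
      if (ch == "-") run <- run + 1L
      else {
        ins[k, cpos + 1L] <- run
        run <- 0L
        cpos <- cpos + 1L
      }
    }
    ins[k, Lc + 1L] <- run
  }
  master_ins <- apply(ins, 2, max)
  pad <- function(row_c, row_s, my_ins) {
    # rebuild row_s against the master gap profile
    out <- character(0)
    chars_c <- strsplit(row_c, "")[[1]]
    chars_s <- strsplit(row_s, "")[[1]]
    cpos <- 0L
    i <- 1L
    emit_block <- function(block, have) {
      c(block, rep("-", master_ins[cpos + 1L] - have))
    }
    block <- character(0)
    for (idx in seq_along(chars_c)) {
      if (chars_c[idx] == "-") {
        block <- c(block, chars_s[idx])
      } else {
        out <- c(out, emit_block(block, length(block)), chars_s[idx])
        block <- character(0)
        cpos <- cpos + 1L
      }
    }
    out <- c(out, emit_block(block, length(block)))
    paste(out, collapse = "")
  }
  # center row: its own insertions are all gaps
  cen_chars <- strsplit(cen_seq, "")[[1]]
  out_c <- character(0)
  for (i in 0:Lc) {
    out_c <- c(out_c, rep("-", master_ins[i + 1L]),
               if (i < Lc) cen_chars[i + 1L] else character(0))
  }
  aligned[[center]] <- paste(out_c, collapse = "")
  for (k in seq_along(others)) {
    aligned[[others[k]]] <- pad(pair_rows[[k]][1], pair_rows[[k]][2],
                                ins[k, ])
  }
  stats::setNames(unlist(aligned), names(members))
}

#' Concatenate cluster alignments and trim gap-rich columns
#'
#' Alignments are concatenated over a shared taxon set and every column
#' whose gap fraction exceeds \code{max_gap_frac} (strictly greater; a
#' column with exactly 50% gaps survives the default) is removed. 'X' is a
#' residue, not a gap. The partition map is reported in post-trim
#' coordinates.
#'
#' @param alignments Named list of alignments (each a named character
#'   vector of equal-length rows over identical taxa).
#' @param max_gap_frac Columns with gap fraction strictly above this are
#'   dropped; default 0.5.
#' @return List: \code{taxa}, \code{rows} (named character vector),
#'   \code{partition_map} (data.frame cluster_id, start, end; 0-width
#'   partitions have end < start).
#' @export
concatenate_and_trim <- function(alignments, max_gap_frac = 0.5) {
  stopifnot(length(alignments) >= 1)
  taxa <- sort(names(alignments[[1]]))
  mats <- list()
  widths <- integer(length(alignments))
  for (k in seq_along(alignments)) {
    aln <- alignments[[k]]
    if (!setequal(names(aln), taxa)) {
      stop("taxa mismatch in cluster '", names(alignments)[k], "'")
    }
    aln <- aln[taxa]
    m <- do.call(rbind, strsplit(aln, ""))
    rownames(m) <- taxa
    mats[[k]] <- m
    widths[k] <- ncol(m)
  }
  full <- do.call(cbind, mats)
  part_id <- rep(names(alignments), widths)
  gap_frac <- colMeans(full == "-")
  keep <- gap_frac <= max_gap_frac
  trimmed <- full[, keep, drop = FALSE]
  kept_part <- part_id[keep]
  pm <- data.frame(cluster_id = names(alignments),
                   start = NA_integer_, end = NA_integer_,
                   stringsAsFactors = FALSE)
  pos <- 0L
  for (k in seq_along(alignments)) {
    w <- sum(kept_part == names(alignments)[k])
    pm$start[k] <- pos + 1L
    pm$end[k] <- pos + w
    pos <- pos + w
  }
  list(taxa = taxa,
       rows = stats::setNames(apply(trimmed, 1, paste, collapse = ""), taxa),
       partition_map = pm)
}

#' Neighbor-joining tree from a trimmed supermatrix
#'
#' Pairwise distances are maximum-likelihood distances under the WAG
#' amino-acid model (via \pkg{phangorn}); the tree is neighbor joining with
#' negative branch lengths clamped to zero.
#'
#' @param sm Supermatrix list from \code{\link{concatenate_and_trim}}.
#' @return An unrooted \code{ape::phylo} tree.
#' @export
build_tree <- function(sm) {
  if (length(sm$taxa) < 3) stop("need at least 3 taxa to build a tree")
  mat <- do.call(rbind, strsplit(sm$rows, ""))
  rownames(mat) <- names(sm$rows)
  pd <- phangorn::phyDat(mat, type = "AA")
  d <- phangorn::dist.ml(pd, model = "WAG")
  tree <- ape::nj(d)
  tree$edge.length[tree$edge.length < 0] <- 0
  ape::unroot(tree)
}

# Non-trivial bipartitions of an unrooted tree as canonical strings.
.bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  n <- length(tips)
  out <- character(0)
  ntip <- length(tree$tip.label)
  # descendants of each internal edge via postorder accumulation
  desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(kids) == 0) return(tree$tip.label[node])
    unlist(lapply(kids, desc))
  }
  internal_children <- tree$edge[, 2][tree$edge[, 2] > ntip]
  for (node in internal_children) {
    side <- sort(desc(node))
    if (length(side) <= 1 || length(side) >= n - 1) next
    other <- setdiff(tips, side)
    canon <- if (tips[1] %in% side) side else other
    out <- c(out, paste(canon, collapse = "|"))
  }
  unique(out)
}

#' Robinson-Foulds distance and tanglegram pairing of two trees
#'
#' RF distance counts bipartitions unique to one of the two unrooted
#' topologies; 0 means identical. The pairing table lists each shared leaf
#' with its position in either tree's ladderised tip order, for tanglegram
#' plotting.
#'
#' @param tree_a,tree_b \code{ape::phylo} trees over the same leaf set.
#' @return List: \code{rf} (integer) and \code{pairing} (data.frame leaf,
#'   pos_a, pos_b).
#' @export
compare_trees <- function(tree_a, tree_b) {
  la <- sort(tree_a$tip.label); lb <- sort(tree_b$tip.label)
  if (!identical(la, lb)) {
    stop("leaf sets differ: ",
         paste(c(setdiff(la, lb), setdiff(lb, la)), collapse = ", "))
  }
  ba <- .bipartitions(tree_a)
  bb <- .bipartitions(tree_b)
  rf <- length(setdiff(ba, bb)) + length(setdiff(bb, ba))
  pairing <- data.frame(leaf = la,
                        pos_a = match(la, tree_a$tip.label),
                        pos_b = match(la, tree_b$tip.label),
                        stringsAsFactors = FALSE)
  list(rf = rf, pairing = pairing)
}
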