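# Independent oracles used across the suite. These deliberately re-derive
# results with different algorithms/code paths than the package.

# Plain-R affine-gap Smith-Waterman (local) score; gap of length k costs
# open + k * ext, matching the package's alignment parameterisation.
sw_score_oracle <- function(a, b, submat, open = 11, ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)  # match state
  E <- matrix(-Inf, n + 1, m + 1)  # gap in b (vertical)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(M[i - 1, j] - open - ext, E[i - 1, j] - ext)
      F[i, j] <- max(M[i, j - 1] - open - ext, F[i, j - 1] - ext)
      M[i, j] <- max(0,
                     max(M[i - 1, j - 1], E[i - 1, j - 1], F[i - 1, j - 1]) +
                       submat[a[i - 1], b[j - 1]])
      best <- max(best, M[i, j], E[i, j], F[i, j])
    }
  }
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Minbit table by brute force from raw Smith-Waterman scores.
minbit_oracle <- function(proteins) {
  ids <- names(proteins)
  self <- vapply(proteins, function(p) sw_score_oracle(p, p, blosum62),
                 numeric(1))
  out <- list()
  n <- length(proteins)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      s <- sw_score_oracle(proteins[[i]], proteins[[j]], blosum62)
      out[[length(out) + 1]] <- data.frame(
        gene_a = ids[i], gene_b = ids[j], raw = s,
        minbit = s / min(self[i], self[j]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Textbook MCL: straightforward loop over expansion and inflation on the
# column-stochastic matrix, clusters read as connected components of the
# thresholded limit matrix (a different read-out than the package's
# attractor-row merge).
mcl_oracle <- function(adj, inflation, iters = 60, prune = 1e-8) {
  diag(adj) <- apply(adj, 1, max)
  diag(adj)[diag(adj) == 0] <- 1
  M <- sweep(adj, 2, colSums(adj), "/")
  for (k in seq_len(iters)) {
    M <- M %*% M
    M <- M^inflation
    M[M < prune] <- 0
    M <- sweep(M, 2, pmax(colSums(M), .Machine$double.xmin), "/")
  }
  G <- (M > 1e-6) | t(M > 1e-6)
  n <- nrow(G)
  comp <- rep(NA_integer_, n)
  cur <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1
    frontier <- i
    while (length(frontier) > 0) {
      comp[frontier] <- cur
      frontier <- setdiff(which(rowSums(G[, frontier, drop = FALSE]) > 0),
                          which(!is.na(comp)))
    }
  }
  stats::setNames(comp, rownames(adj))
}

# Ward (ward.D2) agglomeration via the Lance-Williams recurrence on
# squared distances; returns successive merge heights.
ward_heights_oracle <- function(X) {
  d2 <- as.matrix(stats::dist(X))^2
  n <- nrow(d2)
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(Inf, NA, NA)
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        if (d2[i, j] < best[1]) best <- c(d2[i, j], i, j)
      }
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, sqrt(best[1]))
    for (k in active) {
      if (k == i || k == j) next
      d2[i, k] <- d2[k, i] <-
        ((size[i] + size[k]) * d2[i, k] + (size[j] + size[k]) * d2[j, k] -
           size[k] * d2[i, j]) / (size[i] + size[j] + size[k])
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  heights
}

# Coverage profile built directly from a depth vector (single contig).
profile_from_depth <- function(depth, genome_id = "g", sample_id = "s") {
  list(genome_id = genome_id, sample_id = sample_id,
       depth = as.integer(depth),
       contig_offsets = data.frame(contig_id = paste0(genome_id, "_c1"),
                                   start = 1L, end = length(depth),
                                   stringsAsFactors = FALSE))
}

random_protein <- function(n, alphabet = c("A", "C", "D", "E", "F", "G",
                                           "H", "I", "K", "L", "M", "N",
                                           "P", "Q", "R", "S", "T", "V",
                                           "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

mutate_protein <- function(p, n_subs) {
  ch <- strsplit(p, "")[[1]]
  idx <- sample(seq_along(ch), n_subs)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")
  ch[idx] <- vapply(ch[idx], function(x) sample(setdiff(aas, x), 1),
                    character(1))
  paste(ch, collapse = "")
}

# Tiny toy genome record helper (single contig, all defaults overridable).
toy_genome <- function(id, seq, ...) {
  genome_record(id, stats::setNames(seq, paste0(id, "_c1")), ...)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit) > 0) {
    ch[hit] <- vapply(ch[hit], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), x), 1)
    }, character(1))
  }
  paste(ch, collapse = "")
}
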