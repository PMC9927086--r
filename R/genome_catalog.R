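#' Construct a genome record
#'
#' A genome record bundles one isolate assembly with its manifest metadata:
#' contigs, species label, host, oral/nonoral status, CheckM-style
#' completeness and contamination estimates, and an optional duplicate-strain
#' pointer.
#'
#' @param genome_id Unique genome identifier.
#' @param contigs Named character vector of contig sequences (names are
#'   contig ids).
#' @param species Species label or \code{NA} for genomes identified only to
#'   genus level.
#' @param host Isolation host, e.g. \code{"human"}.
#' @param oral Logical; was the isolate recovered from the oral cavity.
#' @param completeness,contamination Assembly quality estimates in percent.
#' @param duplicate_of \code{NA} or the genome_id this assembly duplicates.
#' @return A list of class \code{genome_record}.
#' @export
genome_record <- function(genome_id, contigs, species = NA_character_,
                          host = "human", oral = TRUE,
                          completeness = 100, contamination = 0,
                          duplicate_of = NA_character_) {
  stopifnot(is.character(contigs), length(contigs) >= 1,
            !is.null(names(contigs)), all(nzchar(names(contigs))))
  if (completeness < 0 || completeness > 100 ||
      contamination < 0 || contamination > 100) {
    stop("completeness and contamination must be in [0, 100] for genome '",
         genome_id, "'")
  }
  structure(list(
    genome_id = as.character(genome_id),
    contigs = contigs,
    species = species,
    host = host,
    oral = isTRUE(oral),
    completeness = completeness,
    contamination = contamination,
    duplicate_of = duplicate_of
  ), class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d contig(s), %s nt, species=%s\n",
              x$genome_id, length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","),
              ifelse(is.na(x$species), "unassigned", x$species)))
  invisible(x)
}

#' Total length of a genome record
#' @param genome A \code{genome_record}.
#' @return Integer, summed contig length in nt.
#' @export
genome_length <- function(genome) sum(nchar(genome$contigs))

#' Remove short contigs and non-canonical nucleotides
#'
#' Contigs shorter than \code{cfg$min_contig_len} are dropped and every
#' letter outside \{A, C, G, T, N\} (e.g. IUPAC ambiguity codes) is replaced
#' with N. Case is normalised to upper.
#'
#' @param genome A \code{genome_record}.
#' @param cfg A \code{\link{selection_config}}.
#' @return The cleaned \code{genome_record}.
#' @export
clean_contigs <- function(genome, cfg = selection_config()) {
  stopifnot(inherits(genome, "genome_record"))
  keep <- nchar(genome$contigs) >= cfg$min_contig_len
  if (!any(keep)) {
    stop("all contigs of genome '", genome$genome_id,
         "' fall below the ", cfg$min_contig_len, " nt minimum")
  }
  contigs <- toupper(genome$contigs[keep])
  contigs <- vapply(contigs, function(s) gsub("[^ACGTN]", "N", s),
                    character(1))
  genome$contigs <- contigs
  genome
}

#' Filter a genome catalog on manifest metadata and assembly quality
#'
#' Retains genomes that (i) come from a human host, (ii) are not flagged as
#' duplicate strains, (iii) have completeness >= \code{min_completeness} and
#' (iv) contamination strictly below \code{max_contamination}. Input order is
#' preserved and the operation is idempotent.
#'
#' @param catalog List of \code{genome_record}s.
#' @param cfg A \code{\link{selection_config}}.
#' @return The retained sub-list.
#' @export
select_genomes <- function(catalog, cfg = selection_config()) {
  if (length(catalog) == 0) return(catalog)
  for (g in catalog) {
    needed <- c("host", "duplicate_of", "completeness", "contamination")
    miss <- needed[vapply(needed, function(f) is.null(g[[f]]), logical(1))]
    if (length(miss) > 0) {
      stop("genome '", g$genome_id, "' is missing manifest field(s): ",
           paste(miss, collapse = ", "))
    }
  }
  keep <- vapply(catalog, function(g) {
    identical(tolower(g$host), "human") &&
      is.na(g$duplicate_of) &&
      g$completeness >= cfg$min_completeness &&
      g$contamination < cfg$max_contamination
  }, logical(1))
  catalog[keep]
}

# Split a sequence into non-overlapping fragments of fragment_len; a
# trailing fragment shorter than half the window is discarded (too short to
# satisfy the coverage floor meaningfully).
.ani_fragments <- function(seq, fragment_len) {
  L <- nchar(seq)
  starts <- seq.int(1L, L, by = fragment_len)
  frags <- substring(seq, starts, pmin(starts + fragment_len - 1L, L))
  frags[nchar(frags) >= max(100L, fragment_len %/% 2L)]
}

# Best local alignment stats of each fragment against a set of subject
# contigs. Returns per-fragment identity (matches / alignment columns) and
# coverage (aligned pattern span / fragment length). Both strands are
# considered; the reverse strand is skipped when the forward hit is already
# strong (identity >= 0.8 with sufficient coverage): a reverse-strand
# alignment of the same fragment cannot beat such a hit outside contrived
# palindromes.
.fragment_hits <- function(fragments, contigs, cfg) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE)
  frag_set <- Biostrings::DNAStringSet(fragments)
  n <- length(fragments)
  best_id <- rep(0, n)
  best_cov <- rep(0, n)
  best_score <- rep(-Inf, n)
  score_one <- function(frag_set) {
    id <- rep(0, n); cov <- rep(0, n); sc <- rep(-Inf, n)
    for (contig in contigs) {
      subj <- Biostrings::DNAString(contig)
      aln <- Biostrings::pairwiseAlignment(
        frag_set, subj, type = "local",
        substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
      s <- Biostrings::score(aln)
      better <- s > sc
      if (any(better)) {
        pid <- Biostrings::pid(aln, type = "PID1") / 100
        span <- Biostrings::width(Biostrings::pattern(aln))
        id[better] <- pid[better]
        cov[better] <- (span / nchar(fragments))[better]
        sc[better] <- s[better]
      }
    }
    list(id = id, cov = cov, sc = sc)
  }
  fwd <- score_one(frag_set)
  need_rev <- !(fwd$id >= 0.8 & fwd$cov >= cfg$ani_min_fragment_coverage)
  if (any(need_rev)) {
    rev <- score_one(Biostrings::reverseComplement(frag_set))
    take <- need_rev & rev$sc > fwd$sc
    fwd$id[take] <- rev$id[take]
    fwd$cov[take] <- rev$cov[take]
  }
  data.frame(identity = fwd$id, coverage = fwd$cov)
}

# One-directional fragment ANI of query genome a against subject b.
.directed_ani <- function(a, b, cfg) {
  fragments <- unlist(lapply(a$contigs, .ani_fragments,
                             fragment_len = cfg$ani_fragment_len),
                      use.names = FALSE)
  if (length(fragments) == 0) return(c(ani = 0, aligned_fraction = 0))
  hits <- .fragment_hits(fragments, b$contigs, cfg)
  ok <- hits$coverage >= cfg$ani_min_fragment_coverage &
    hits$identity >= cfg$ani_min_fragment_identity
  if (!any(ok)) return(c(ani = 0, aligned_fraction = 0))
  c(ani = mean(hits$identity[ok]),
    aligned_fraction = sum(ok) / length(fragments))
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' The query genome is cut into non-overlapping windows
#' (\code{cfg$ani_fragment_len}, default 1020 nt); each window is aligned
#' locally (match +1 / mismatch -1 / gap open -5 / extend -2, both strands)
#' against the subject, and windows passing the coverage (>= 0.7) and
#' identity (>= 0.3) floors contribute their identity to the mean. Both
#' directed estimates are computed and averaged, which makes the result
#' symmetric by construction.
#'
#' @param a,b \code{genome_record}s (cleaned).
#' @param cfg A \code{\link{selection_config}}.
#' @return A one-row data.frame: genome_a, genome_b, ani, aligned_fraction.
#'   If no fragment is accepted in either direction, ani and
#'   aligned_fraction are 0.
#' @export
compute_ani <- function(a, b, cfg = selection_config()) {
  ab <- .directed_ani(a, b, cfg)
  ba <- .directed_ani(b, a, cfg)
  data.frame(genome_a = a$genome_id, genome_b = b$genome_id,
             ani = unname((ab["ani"] + ba["ani"]) / 2),
             aligned_fraction =
               unname((ab["aligned_fraction"] + ba["aligned_fraction"]) / 2),
             stringsAsFactors = FALSE)
}

#' All-pairs ANI table for a catalog
#'
#' @param catalog List of cleaned \code{genome_record}s.
#' @param cfg A \code{\link{selection_config}}.
#' @return data.frame with one row per unordered genome pair.
#' @export
ani_matrix <- function(catalog, cfg = selection_config()) {
  n <- length(catalog)
  rows <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        rows[[length(rows) + 1L]] <- compute_ani(catalog[[i]], catalog[[j]], cfg)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(genome_a = character(), genome_b = character(),
                      ani = numeric(), aligned_fraction = numeric()))
  }
  do.call(rbind, rows)
}

# Symmetric lookup of a pairwise ANI value; errors on a missing pair.
.ani_lookup <- function(ani, ids) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  tab <- stats::setNames(ani$ani, key(ani$genome_a, ani$genome_b))
  function(a, b) {
    v <- unname(tab[key(a, b)])
    if (is.na(v)) stop("ANI table is missing the pair (", a, ", ", b, ")")
    v
  }
}

#' Dereplicate a catalog at an ANI threshold
#'
#' Greedy deterministic dereplication: genomes are ranked by completeness
#' (descending), then total assembly length (descending), then genome_id
#' (ascending); each unclaimed genome in turn becomes a representative and
#' claims every remaining genome sharing ANI > \code{cfg$derep_ani} with it.
#' No two representatives exceed the threshold and every removed genome
#' exceeds it with its representative.
#'
#' @param catalog List of \code{genome_record}s.
#' @param ani All-pairs ANI data.frame (see \code{\link{ani_matrix}});
#'   must cover every pair in \code{catalog}.
#' @param cfg A \code{\link{selection_config}}.
#' @return The representative sub-list, in original catalog order.
#' @export
dereplicate <- function(catalog, ani, cfg = selection_config()) {
  if (length(catalog) <= 1) return(catalog)
  ids <- vapply(catalog, `[[`, character(1), "genome_id")
  lookup <- .ani_lookup(ani, ids)
  if (length(ids) >= 2) {
    pairs <- t(utils::combn(ids, 2))
    for (k in seq_len(nrow(pairs))) lookup(pairs[k, 1], pairs[k, 2])
  }
  comp <- vapply(catalog, `[[`, numeric(1), "completeness")
  len <- vapply(catalog, genome_length, numeric(1))
  ord <- order(-comp, -len, ids)
  claimed <- rep(FALSE, length(catalog))
  rep_flag <- rep(FALSE, length(catalog))
  for (i in ord) {
    if (claimed[i]) next
    rep_flag[i] <- TRUE
    claimed[i] <- TRUE
    for (j in seq_along(catalog)) {
      if (!claimed[j] && lookup(ids[i], ids[j]) > cfg$derep_ani) {
        claimed[j] <- TRUE
      }
    }
  }
  catalog[rep_flag]
}

#' Group genomes into species-level clades by single-linkage ANI
#'
#' Builds the graph connecting genome pairs with ANI >= \code{threshold}
#' (95% is the conventional bacterial species boundary) and returns its
#' connected components.
#'
#' @param ids Character vector of genome ids.
#' @param ani All-pairs ANI data.frame covering \code{ids}.
#' @param threshold Linkage threshold, default 0.95.
#' @return Named integer vector: component label per genome id.
#' @export
ani_species_groups <- function(ids, ani, threshold = 0.95) {
  lookup <- .ani_lookup(ani, ids)
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        if (lookup(ids[i], ids[j]) >= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  stats::setNames(match(roots, unique(roots)), ids)
}
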