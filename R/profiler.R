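#' Read a plain-text SAM file into an alignment table
#'
#' Minimal parser for the columns the profiler needs: reference name,
#' 1-based leftmost position and CIGAR. Header lines (@) are skipped;
#' unmapped records (rname "*" or flag bit 0x4) are dropped. Inputs need
#' not be sorted.
#'
#' @param path Path to a SAM text file.
#' @return data.frame: qname, flag, rname, pos, cigar.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      cigar = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) < 6
  if (any(bad)) stop("malformed SAM record at line(s): ",
                     paste(utils::head(which(bad)), collapse = ", "))
  out <- data.frame(
    qname = vapply(fields, `[[`, character(1), 1),
    flag = as.integer(vapply(fields, `[[`, character(1), 2)),
    rname = vapply(fields, `[[`, character(1), 3),
    pos = as.integer(vapply(fields, `[[`, character(1), 4)),
    cigar = vapply(fields, `[[`, character(1), 6),
    stringsAsFactors = FALSE)
  out[out$rname != "*" & bitwAnd(out$flag, 4L) == 0L, , drop = FALSE]
}

#' Write an alignment table as plain-text SAM
#'
#' @param alignments data.frame with qname, rname, pos, cigar (flag
#'   optional, defaults 0).
#' @param contig_lengths Named integer vector for the @SQ header lines.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sam <- function(alignments, contig_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  flag <- if ("flag" %in% names(alignments)) alignments$flag else 0L
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
                  alignments$qname, flag, alignments$rname,
                  alignments$pos, alignments$cigar)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Reference span consumed by a CIGAR string: M/=/X/D/N consume reference;
# I/S/H/P do not. Returns per-operation (len, consumes, adds_depth).
.cigar_ref_ops <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  list(lens = lens, ops = ops)
}

#' Per-nucleotide coverage profiles from read alignments
#'
#' Depth at a position counts the alignments whose reference span covers
#' it: CIGAR M/=/X add depth, D/N consume reference without adding depth,
#' I/S/H are ignored on the reference. Coordinates are 1-based inclusive at
#' the SAM boundary and held as one depth vector per genome over its
#' concatenated contigs.
#'
#' @param alignments Alignment data.frame (see \code{\link{read_sam}}).
#' @param genomes List of cleaned \code{genome_record}s; contig ids must be
#'   unique across the set (competitive mapping against one concatenated
#'   reference).
#' @param sample_id Sample label stored on each profile.
#' @return Named list (genome_id) of coverage profiles; each a list with
#'   \code{genome_id}, \code{sample_id}, \code{depth} (integer vector) and
#'   \code{contig_offsets} (data.frame contig_id, start, end into depth).
#' @export
coverage_from_alignments <- function(alignments, genomes,
                                     sample_id = NA_character_) {
  contig_genome <- list()
  profiles <- list()
  for (g in genomes) {
    L <- genome_length(g)
    ends <- cumsum(nchar(g$contigs))
    starts <- c(1L, utils::head(ends, -1) + 1L)
    profiles[[g$genome_id]] <- list(
      genome_id = g$genome_id, sample_id = sample_id,
      depth = integer(L),
      contig_offsets = data.frame(contig_id = names(g$contigs),
                                  start = starts, end = ends,
                                  stringsAsFactors = FALSE))
    for (cid in names(g$contigs)) contig_genome[[cid]] <- g$genome_id
  }
  if (nrow(alignments) == 0) return(profiles)
  unknown <- setdiff(unique(alignments$rname), names(contig_genome))
  if (length(unknown) > 0) {
    stop("alignment references unknown contig(s): ",
         paste(unknown, collapse = ", "))
  }
  for (k in seq_len(nrow(alignments))) {
    cid <- alignments$rname[k]
    gid <- contig_genome[[cid]]
    off <- profiles[[gid]]$contig_offsets
    base <- off$start[off$contig_id == cid] - 1L
    contig_end <- off$end[off$contig_id == cid] - base
    ref <- alignments$pos[k]
    cig <- .cigar_ref_ops(alignments$cigar[k])
    for (i in seq_along(cig$ops)) {
      op <- cig$ops[i]; len <- cig$lens[i]
      if (op %in% c("M", "=", "X")) {
        span <- seq.int(ref, min(ref + len - 1L, contig_end))
        profiles[[gid]]$depth[base + span] <-
          profiles[[gid]]$depth[base + span] + 1L
        ref <- ref + len
      } else if (op %in% c("D", "N")) {
        ref <- ref + len
      }
    }
  }
  profiles
}

#' Breadth of coverage of a profile
#'
#' Fraction of positions with depth at least \code{min_depth}.
#'
#' @param profile A coverage profile.
#' @param min_depth Depth threshold, default 1.
#' @return Fraction in [0, 1].
#' @export
breadth <- function(profile, min_depth = 1L) {
  stopifnot(length(profile$depth) > 0)
  mean(profile$depth >= min_depth)
}

#' Genome-level detection rule
#'
#' A genome is detected in a metagenome when breadth of coverage is at
#' least \code{cfg$genome_breadth_min} (inclusive; default 50%).
#'
#' @param profile A coverage profile.
#' @param cfg A \code{\link{detection_config}}.
#' @return Logical.
#' @export
detect_genome <- function(profile, cfg = detection_config()) {
  breadth(profile, cfg$min_depth) >= cfg$genome_breadth_min
}

#' Gene-level detection rule
#'
#' A gene is detected when at least \code{cfg$gene_breadth_min} (default
#' 90%) of its nucleotide positions have depth >= 1.
#'
#' @param profile A coverage profile for the gene's genome.
#' @param gene One row of a gene-call data.frame (contig_id, start, stop).
#' @param cfg A \code{\link{detection_config}}.
#' @return Logical.
#' @export
detect_gene <- function(profile, gene, cfg = detection_config()) {
  off <- profile$contig_offsets
  row <- off[off$contig_id == gene$contig_id, , drop = FALSE]
  if (nrow(row) != 1) stop("gene contig '", gene$contig_id,
                           "' not in profile for ", profile$genome_id)
  contig_len <- row$end - row$start + 1L
  if (gene$start < 1 || gene$stop > contig_len) {
    stop("gene '", gene$gene_id, "' exceeds contig bounds")
  }
  span <- (row$start - 1L) + seq.int(gene$start, gene$stop)
  mean(profile$depth[span] >= cfg$min_depth) >= cfg$gene_breadth_min
}

#' Interquartile mean depth of coverage
#'
#' Depths are ranked ascending and positions with 0-based sorted index in
#' [floor(L/4), ceil(3L/4)) are averaged, so exactly the middle half is used
#' when L is divisible by 4 and at least half otherwise. Returns 0 for an
#' all-zero profile.
#'
#' @param profile A coverage profile (length >= 4).
#' @return Mean depth over the interquartile positions.
#' @export
q2q3_mean <- function(profile) {
  L <- length(profile$depth)
  if (L < 4) stop("q2q3_mean needs a profile of length >= 4")
  d <- sort(profile$depth)
  idx <- seq.int(floor(L / 4) + 1L, ceiling(3 * L / 4))
  mean(d[idx])
}

#' Per-sample relative abundance over a genome set
#'
#' Each genome's interquartile mean depth is divided by the summed
#' interquartile mean depth of the denominator set — all reference genomes
#' by default, or only the detected ones with \code{denominator =
#' "detected"}. Undetected genomes are reported (detected = FALSE) and, in
#' the default mode, still contribute to the denominator. If the
#' denominator is 0 all abundances are 0 and the rows are flagged.
#'
#' @param profiles Named list of coverage profiles for one sample.
#' @param cfg A \code{\link{detection_config}}.
#' @param denominator "all" (default) or "detected".
#' @return data.frame: sample_id, genome_id, detected, q2q3_mean,
#'   rel_abundance, flagged.
#' @export
relative_abundance <- function(profiles, cfg = detection_config(),
                               denominator = c("all", "detected")) {
  denominator <- match.arg(denominator)
  q <- vapply(profiles, q2q3_mean, numeric(1))
  det <- vapply(profiles, detect_genome, logical(1), cfg = cfg)
  denom <- if (denominator == "all") sum(q) else sum(q[det])
  rel <- if (denom > 0) {
    if (denominator == "all") q / denom else ifelse(det, q / denom, 0)
  } else rep(0, length(q))
  data.frame(
    sample_id = vapply(profiles, `[[`, character(1), "sample_id"),
    genome_id = names(profiles),
    detected = det, q2q3_mean = unname(q), rel_abundance = unname(rel),
    flagged = denom == 0, row.names = NULL, stringsAsFactors = FALSE)
}

#' Roll genome abundances up to species per sample
#'
#' Species abundance is the sum of its member genomes' relative abundances;
#' a species is detected when any member genome is. Samples where no genome
#' at all was detected are dropped from the output.
#'
#' @param table Abundance data.frame from \code{\link{relative_abundance}}
#'   (possibly several samples row-bound).
#' @param species_map Named character vector: genome_id -> species.
#' @return data.frame: sample_id, species, detected, rel_abundance.
#' @export
species_rollup <- function(table, species_map) {
  unmapped <- setdiff(unique(table$genome_id), names(species_map))
  if (length(unmapped) > 0) {
    stop("genome(s) not in species map: ", paste(unmapped, collapse = ", "))
  }
  table$species <- unname(species_map[table$genome_id])
  keep_samples <- unique(table$sample_id[table$detected])
  table <- table[table$sample_id %in% keep_samples, , drop = FALSE]
  if (nrow(table) == 0) {
    return(data.frame(sample_id = character(), species = character(),
                      detected = logical(), rel_abundance = numeric()))
  }
  agg <- stats::aggregate(
    cbind(rel_abundance = table$rel_abundance,
          detected = as.integer(table$detected)),
    by = list(sample_id = table$sample_id, species = table$species), sum)
  agg$detected <- agg$detected > 0
  agg[order(agg$sample_id, agg$species),
      c("sample_id", "species", "detected", "rel_abundance")]
}
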