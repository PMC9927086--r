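#' Genome selection and ANI configuration
#'
#' Thresholds governing contig cleaning, genome quality filtering and
#' fragment-based ANI dereplication.
#'
#' @param min_contig_len Minimum contig length kept, in nt (contigs shorter
#'   than this are dropped).
#' @param min_completeness Minimum assembly completeness retained, percent.
#' @param max_contamination Contamination must be strictly below this,
#'   percent.
#' @param derep_ani Dereplication threshold as a fraction: genomes sharing
#'   ANI above this are collapsed to one representative.
#' @param ani_fragment_len Length of the non-overlapping query fragments
#'   used for ANI estimation, nt.
#' @param ani_min_fragment_identity Minimum alignment identity for a
#'   fragment to be accepted.
#' @param ani_min_fragment_coverage Minimum fraction of the fragment covered
#'   by its best local alignment for acceptance.
#' @return A list of class \code{selection_config}.
#' @export
selection_config <- function(min_contig_len = 300L,
                             min_completeness = 90,
                             max_contamination = 5,
                             derep_ani = 0.98,
                             ani_fragment_len = 1020L,
                             ani_min_fragment_identity = 0.3,
                             ani_min_fragment_coverage = 0.7) {
  stopifnot(derep_ani > 0, derep_ani < 1, ani_fragment_len > 0,
            min_contig_len >= 1)
  structure(list(
    min_contig_len = as.integer(min_contig_len),
    min_completeness = min_completeness,
    max_contamination = max_contamination,
    derep_ani = derep_ani,
    ani_fragment_len = as.integer(ani_fragment_len),
    ani_min_fragment_identity = ani_min_fragment_identity,
    ani_min_fragment_coverage = ani_min_fragment_coverage
  ), class = "selection_config")
}

#' Detection thresholds for read-recruitment profiling
#'
#' @param genome_breadth_min Minimum breadth of coverage (fraction of
#'   positions at >= \code{min_depth}) for a genome to count as detected.
#' @param gene_breadth_min Minimum breadth over a gene's positions for
#'   gene-level detection.
#' @param min_depth Depth a position must reach to count as covered.
#' @return A list of class \code{detection_config}.
#' @export
detection_config <- function(genome_breadth_min = 0.5,
                             gene_breadth_min = 0.9,
                             min_depth = 1L) {
  stopifnot(genome_breadth_min > 0, genome_breadth_min <= 1,
            gene_breadth_min > 0, gene_breadth_min <= 1, min_depth >= 1)
  structure(list(
    genome_breadth_min = genome_breadth_min,
    gene_breadth_min = gene_breadth_min,
    min_depth = as.integer(min_depth)
  ), class = "detection_config")
}
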