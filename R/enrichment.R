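#' Metabolic-module completeness in one genome
#'
#' A module is an ordered list of steps, each a set of alternative
#' orthology accessions (OR semantics); a step is satisfied when the genome
#' carries any alternative. Completeness is satisfied steps / total steps,
#' and the module is "complete" at fraction >= \code{threshold} (inclusive;
#' default 0.75).
#'
#' @param accessions Character vector of accessions annotated in the
#'   genome (within the module's namespace).
#' @param module List with \code{module_id} and \code{steps} (list of
#'   character vectors).
#' @param threshold Completion threshold, default 0.75.
#' @return List: \code{fraction}, \code{complete}.
#' @export
module_completeness <- function(accessions, module, threshold = 0.75) {
  if (length(module$steps) == 0) {
    stop("module '", module$module_id, "' has no steps")
  }
  sat <- vapply(module$steps, function(alts) any(alts %in% accessions),
                logical(1))
  frac <- mean(sat)
  list(fraction = frac, complete = frac >= threshold)
}

#' Completeness matrix for a set of genomes and modules
#'
#' @param annotations data.frame with genome_id and accession columns.
#' @param modules Named list of module definitions.
#' @param threshold Completion threshold passed through.
#' @return List: \code{fraction} and \code{complete} matrices
#'   (genomes x modules).
#' @export
completeness_matrix <- function(annotations, modules, threshold = 0.75) {
  genomes <- sort(unique(annotations$genome_id))
  acc_by_genome <- split(annotations$accession, annotations$genome_id)
  frac <- matrix(0, length(genomes), length(modules),
                 dimnames = list(genomes, names(modules)))
  for (g in genomes) {
    for (m in names(modules)) {
      frac[g, m] <- module_completeness(acc_by_genome[[g]], modules[[m]],
                                        threshold)$fraction
    }
  }
  list(fraction = frac, complete = frac >= threshold)
}

#' Logistic score test for group association of a presence pattern
#'
#' Rao score statistic of the logistic regression presence ~ group against
#' the intercept-only null, with a chi-square reference on (groups - 1)
#' degrees of freedom. A presence pattern that is identical across all
#' genomes carries no information and returns score 0, p 1.
#'
#' @param presence Logical vector, one entry per genome.
#' @param groups Group label per genome (>= 2 distinct, each nonempty).
#' @return List: \code{score}, \code{p},
#'   \code{group_present_fractions} (named numeric).
#' @export
enrichment_test <- function(presence, groups) {
  stopifnot(length(presence) == length(groups))
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    stop("enrichment test needs at least 2 nonempty groups")
  }
  groups <- droplevels(groups)
  fracs <- tapply(as.numeric(presence), groups, mean)
  if (all(presence) || all(!presence)) {
    return(list(score = 0, p = 1,
                group_present_fractions = as.vector(fracs) |>
                  stats::setNames(levels(groups))))
  }
  y <- as.numeric(presence)
  fit0 <- stats::glm(y ~ 1, family = stats::binomial())
  fit1 <- suppressWarnings(
    stats::glm(y ~ groups, family = stats::binomial()))
  tab <- suppressWarnings(stats::anova(fit0, fit1, test = "Rao"))
  score <- tab$Rao[2]
  if (is.na(score) || score < 0) score <- 0
  p <- stats::pchisq(score, df = nlevels(groups) - 1, lower.tail = FALSE)
  list(score = unname(score), p = unname(p),
       group_present_fractions = as.vector(fracs) |>
         stats::setNames(levels(groups)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector in [0, 1].
#' @return q-values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1 | is.na(pvalues))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Test modules for enrichment between site-specialist genome groups
#'
#' Each module's complete/incomplete indicator (completeness >=
#' \code{threshold}) is tested for association with group membership in
#' every pairwise group comparison; p-values are BH-adjusted within each
#' comparison and results with q <= \code{q_threshold} are flagged
#' enriched. Group assignment (genome -> site-preference group) is an
#' explicit input derived from the detection/abundance stage, never
#' inferred here.
#'
#' @param complete Logical genomes x modules matrix (from
#'   \code{\link{completeness_matrix}}).
#' @param groups Named group label per genome (names = rownames of
#'   \code{complete}).
#' @param q_threshold Enrichment call threshold, default 0.01.
#' @return data.frame: comparison, item_id, per-group present fractions
#'   (comma-separated "group=frac"), score, p, q, enriched; sorted by
#'   comparison then q.
#' @export
enriched_modules <- function(complete, groups, q_threshold = 0.01) {
  stopifnot(!is.null(rownames(complete)))
  groups <- groups[rownames(complete)]
  if (any(is.na(groups))) stop("every genome needs a group label")
  levs <- sort(unique(as.character(groups)))
  out <- list()
  for (i in seq_along(levs)) {
    for (j in seq_along(levs)) {
      if (j <= i) next
      sel <- groups %in% c(levs[i], levs[j])
      cmp <- paste(levs[i], "vs", levs[j])
      res <- lapply(colnames(complete), function(m) {
        r <- enrichment_test(complete[sel, m], groups[sel])
        data.frame(comparison = cmp, item_id = m,
                   group_present_fractions = paste(
                     sprintf("%s=%.3f", names(r$group_present_fractions),
                             r$group_present_fractions), collapse = ","),
                   score = r$score, p = r$p, stringsAsFactors = FALSE)
      })
      res <- do.call(rbind, res)
      res$q <- bh_adjust(res$p)
      res$enriched <- res$q <= q_threshold
      out[[cmp]] <- res[order(res$q, res$item_id), ]
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
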