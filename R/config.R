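#' Runtime configuration for an IKAP sweep
#'
#' Collects every tunable of the pipeline with the defaults used throughout:
#' the initial-resolution heuristic for \code{k_max}, the nPC search span, the
#' resolution schedule for the initial fine partition, the number of uniform
#' reference draws for the gap statistic, differential-expression thresholds,
#' and the decision-tree split range.
#'
#' @param r_ini resolution used to estimate \code{k_max} (default 1.5).
#' @param npc_span width of the nPC sweep, \code{nPC_max - nPC_min} (default 20).
#' @param r_start,r_step,r_cap resolution schedule for the initial partition:
#'   start at \code{r_start}, increase by \code{r_step} until the partition has
#'   at least \code{k_max} groups, error past \code{r_cap}.
#' @param gap_B number of uniform reference draws per gap statistic.
#' @param seed integer seed; every stochastic step derives its stream from it.
#' @param nsplit_range inclusive range of decision-tree split counts averaged
#'   into the final classification error.
#' @param auroc_cutoffs AUROC cutoffs for the high-AUROC DE-gene counts.
#' @param min_logfc,min_pct,max_padj DE-gene thresholds: minimum natural-log
#'   fold change, minimum expressing fraction (in- or out-of-group), maximum
#'   Bonferroni-adjusted p-value.
#' @param min_cells_recurse minimum number of cells for a run (and for
#'   recursing into a group when building an ontology).
#' @param min_genes,max_mito_frac cell-filter thresholds (see
#'   \code{\link{filter_cells}}).
#' @param n_pcs number of principal components computed before the sweep;
#'   capped at \code{min(genes, cells) - 1}.
#' @param knn,snn_prune shared-nearest-neighbor graph parameters: neighbor
#'   count and Jaccard pruning threshold.
#' @param dispersion_norm \code{"normalized"} divides each group's pairwise
#'   distance sum by twice the group size (the gap-statistic convention);
#'   \code{"raw_sum"} uses the plain sum.
#' @param gap_reference how uniform reference draws are partitioned:
#'   \code{"kmeans"} (seeded, 10 restarts) or \code{"merge"} (the same
#'   cluster-and-merge pipeline used on the observed data; slower, for
#'   fidelity experiments).
#' @param candidate_sd_mult multiplier on the standard deviation in the
#'   gap-increase filter threshold \code{mean + mult * sd}.
#'
#' @return an object of class \code{"ikap_config"} (a validated list).
#' @export
ikap_config <- function(r_ini = 1.5, npc_span = 20L,
                        r_start = 1.0, r_step = 0.2, r_cap = 5.0,
                        gap_B = 100L, seed = 0L,
                        nsplit_range = c(5L, 15L),
                        auroc_cutoffs = c(0.8, 0.85, 0.9),
                        min_logfc = 0.25, min_pct = 0.1, max_padj = 0.05,
                        min_cells_recurse = 100L,
                        min_genes = 200L, max_mito_frac = 0.05,
                        n_pcs = 40L, knn = 20L, snn_prune = 1 / 15,
                        dispersion_norm = c("normalized", "raw_sum"),
                        gap_reference = c("kmeans", "merge"),
                        candidate_sd_mult = 1) {
  cfg <- list(
    r_ini = as.numeric(r_ini), npc_span = as.integer(npc_span),
    r_start = as.numeric(r_start), r_step = as.numeric(r_step),
    r_cap = as.numeric(r_cap),
    gap_B = as.integer(gap_B), seed = as.integer(seed),
    nsplit_range = as.integer(nsplit_range),
    auroc_cutoffs = as.numeric(auroc_cutoffs),
    min_logfc = as.numeric(min_logfc), min_pct = as.numeric(min_pct),
    max_padj = as.numeric(max_padj),
    min_cells_recurse = as.integer(min_cells_recurse),
    min_genes = as.integer(min_genes),
    max_mito_frac = as.numeric(max_mito_frac),
    n_pcs = as.integer(n_pcs), knn = as.integer(knn),
    snn_prune = as.numeric(snn_prune),
    dispersion_norm = match.arg(dispersion_norm),
    gap_reference = match.arg(gap_reference),
    candidate_sd_mult = as.numeric(candidate_sd_mult)
  )
  stopifnot(
    cfg$r_ini > 0, cfg$npc_span >= 0, cfg$gap_B >= 1,
    length(cfg$nsplit_range) == 2L,
    cfg$nsplit_range[1] <= cfg$nsplit_range[2],
    cfg$r_start > 0, cfg$r_step > 0, cfg$r_cap >= cfg$r_start,
    cfg$min_pct >= 0, cfg$min_pct <= 1,
    cfg$max_mito_frac >= 0, cfg$max_mito_frac <= 1,
    cfg$min_cells_recurse >= 1, cfg$knn >= 1
  )
  class(cfg) <- "ikap_config"
  cfg
}

#' @export
print.ikap_config <- function(x, ...) {
  cat("IKAP configuration:\n")
  flat <- vapply(x, function(v) paste(format(v), collapse = " "), character(1))
  for (nm in names(flat)) cat(sprintf("  %-18s %s\n", nm, flat[[nm]]))
  invisible(x)
}

# derive a reproducible sub-seed from the master seed; kept well below 2^31
.sub_seed <- function(seed, ...) {
  parts <- c(...)
  s <- as.double(seed) %% 1000003
  for (p in parts) s <- (s * 131 + as.double(p)) %% 1000003
  as.integer(s)
}
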