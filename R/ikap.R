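#' Identify major cell groups by a systematic (nPC, k) sweep
#'
#' The full pipeline: cells are filtered and log-normalized; variable genes
#' are selected; total-UMI and mitochondrial-fraction covariates are
#' regressed out and the matrix scaled; principal components are computed;
#' the (nPC, k) search space is determined automatically; for every nPC a
#' fine partition is merged into nested groupings scored by the gap
#' statistic; candidate (nPC, k) sets are picked from the gap-increase matrix
#' by a greedy rule; each candidate's groups are characterized by one-vs-rest
#' DE genes and a decision-tree classification error; and the candidate with
#' the lowest error is marked best. Fully seeded and reproducible.
#'
#' @param x a \code{"raw_counts"} object, a genes-by-cells count matrix with
#'   dimnames, or a path accepted by \code{\link{read_counts}}.
#' @param config an \code{\link{ikap_config}}.
#' @param covariates per-cell covariates regressed out before scaling;
#'   \code{NULL} (default) uses total UMI count and mitochondrial fraction,
#'   \code{NA} disables regression, otherwise a numeric matrix / data.frame
#'   with one row per (filtered) cell.
#' @param filter whether to apply the cell filter (disable for datasets that
#'   are already curated).
#' @param ... passed to \code{\link{read_counts}} when \code{x} is a path.
#' @return an object of class \code{"ikap"}: list with \code{bounds},
#'   \code{gap} (gap / gap-increase matrices and grouping series),
#'   \code{candidates} (each with grouping, DE table and classifier report),
#'   \code{summary}, \code{best}, \code{selection_threshold},
#'   \code{variable_genes}, \code{cell_ids}, \code{config}.
#' @seealso \code{\link{build_ontology}} for recursive application,
#'   \code{\link{write_results}} for on-disk reports.
#' @export
ikap <- function(x, config = ikap_config(), covariates = NULL,
                 filter = TRUE, ...) {
  raw <- if (inherits(x, "raw_counts")) x
    else if (is.character(x)) read_counts(x, ...)
    else raw_counts(x)
  if (filter)
    raw <- filter_cells(raw, config$min_genes, config$max_mito_frac)
  if (ncol(raw$matrix) < config$min_cells_recurse)
    stop("only ", ncol(raw$matrix), " cells after filtering; at least ",
         config$min_cells_recurse, " required")
  norm <- normalize_counts(raw)
  vg <- select_variable_genes(norm)
  cov <- if (is.null(covariates)) {
    cbind(total_umi = norm$total_umi, mito_frac = norm$mito_frac)
  } else if (length(covariates) == 1 && is.na(covariates)) {
    NULL
  } else covariates
  scaled <- regress_and_scale(norm, cov, genes = vg)
  n_pcs <- min(config$n_pcs, min(dim(scaled$matrix)) - 1L)
  pc <- compute_pca(scaled, n_pcs)
  bounds <- sweep_bounds(pc, config)
  gm <- gap_increase_matrix(pc, bounds, config)
  picks <- select_candidates(gm, sd_mult = config$candidate_sd_mult)
  candidates <- materialize_candidates(picks, gm$series)
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    cand$de <- find_de_genes(norm, cand$grouping, config$min_logfc,
                             config$min_pct, config$max_padj)
    cand$classifier <- classification_error(norm, cand$grouping, cand$de,
                                            config$nsplit_range)
    candidates[[i]] <- cand
  }
  summ <- summarize_candidates(candidates, config$auroc_cutoffs)
  structure(list(bounds = bounds,
                 gap = gm[c("gap", "increase", "B", "seed", "series")],
                 candidates = candidates,
                 summary = summ, best = summ$best,
                 selection_threshold = attr(picks, "threshold"),
                 variable_genes = vg,
                 cell_ids = raw$cell_ids,
                 raw = raw, norm = norm,
                 config = config),
            class = "ikap")
}

#' @export
print.ikap <- function(x, ...) {
  cat(sprintf("IKAP sweep of %d cells: nPC %d..%d, k up to %d\n",
              length(x$cell_ids), x$bounds$nPC_min, x$bounds$nPC_max,
              x$bounds$k_max))
  tab <- x$summary$table
  cat(sprintf("%d candidate set(s); best: %s (classification error %.4f)\n",
              nrow(tab), tab$name[x$best],
              tab$classification_error[x$best]))
  invisible(x)
}

#' @export
summary.ikap <- function(object, ...) {
  tab <- object$summary$table
  class(tab) <- c("summary.ikap", "data.frame")
  tab
}

#' @export
print.summary.ikap <- function(x, ...) {
  cat("Candidate major-group sets:\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Cell-to-group assignment of a candidate set
#'
#' @param object an \code{"ikap"} result.
#' @param candidate candidate index or name (default: the best set).
#' @return data.frame with \code{cell_id} and integer \code{group}.
#' @export
cell_groups <- function(object, candidate = NULL) {
  stopifnot(inherits(object, "ikap"))
  i <- .resolve_candidate(object, candidate)
  data.frame(cell_id = object$cell_ids,
             group = object$candidates[[i]]$grouping$labels)
}

.resolve_candidate <- function(object, candidate) {
  if (is.null(candidate)) return(object$best)
  if (is.character(candidate)) {
    i <- match(candidate,
               vapply(object$candidates, `[[`, character(1), "name"))
    if (is.na(i)) stop("no candidate named ", candidate)
    return(i)
  }
  stopifnot(candidate >= 1, candidate <= length(object$candidates))
  as.integer(candidate)
}

#' Plot the gap-increase matrix of a sweep
#'
#' Displays M(nPC, k) as a shaded image with the accepted candidates marked.
#'
#' @param x an \code{"ikap"} result.
#' @param ... further arguments passed to \code{image}.
#' @export
plot.ikap <- function(x, ...) {
  m <- x$gap$increase
  npcs <- as.integer(rownames(m))
  ks <- as.integer(colnames(m))
  graphics::image(npcs, ks, m, xlab = "nPC", ylab = "k",
                  main = "gap increase M(nPC, k)", ...)
  for (cand in x$candidates)
    graphics::points(cand$nPC, cand$k, pch = 4, cex = 2, lwd = 2)
  invisible(x)
}

#' Benchmark grid of fixed-parameter trial clusterings
#'
#' Clusters the data on a fixed grid of (nPC, resolution) pairs — by default
#' nPC in {5, 10, 15, 20} and r in {0.1, 0.2, 0.4, 0.6, 1.0}, the 20-trial
#' grid — and evaluates each trial grouping with the same DE /
#' classification-error metrics applied to the sweep's candidates, for
#' comparing the sweep against the trial-and-error strategy.
#'
#' @param x input accepted by \code{\link{ikap}}.
#' @param npcs,resolutions grid axes.
#' @param config an \code{\link{ikap_config}}.
#' @param filter whether to apply the cell filter.
#' @return data.frame with one row per trial (name "PC<nPC>R<r>", k, the
#'   AUROC-count metrics, median top-10 log fold change and classification
#'   error).
#' @export
trial_grid <- function(x, npcs = c(5, 10, 15, 20),
                       resolutions = c(0.1, 0.2, 0.4, 0.6, 1.0),
                       config = ikap_config(), filter = TRUE) {
  raw <- if (inherits(x, "raw_counts")) x else raw_counts(x)
  if (filter)
    raw <- filter_cells(raw, config$min_genes, config$max_mito_frac)
  norm <- normalize_counts(raw)
  vg <- select_variable_genes(norm)
  scaled <- regress_and_scale(
    norm, cbind(total_umi = norm$total_umi, mito_frac = norm$mito_frac),
    genes = vg)
  pc <- compute_pca(scaled, min(config$n_pcs, min(dim(scaled$matrix)) - 1L,
                                max(npcs)))
  npcs <- npcs[npcs <= ncol(pc$scores)]
  rows <- list()
  for (npc in npcs) for (r in resolutions) {
    g <- cluster_cells(pc, npc, r, seed = .sub_seed(config$seed, npc, r * 10),
                       knn = config$knn, prune = config$snn_prune)
    cand <- list(name = sprintf("PC%dR%g", npc, r), nPC = npc, k = g$k,
                 gap_increase = NA_real_, grouping = g)
    if (g$k >= 2) {
      cand$de <- find_de_genes(norm, g, config$min_logfc, config$min_pct,
                               config$max_padj)
      cand$classifier <- if (nrow(cand$de) > 0)
        classification_error(norm, g, cand$de, config$nsplit_range)
      else list(final_error = NA_real_)
      rows[[length(rows) + 1L]] <-
        summarize_candidates(list(cand), config$auroc_cutoffs)$table
    }
  }
  if (length(rows) == 0) {
    warning("no trial clustering produced 2 or more groups")
    return(data.frame())
  }
  tab <- do.call(rbind, rows)
  tab$is_best <- NULL
  rownames(tab) <- NULL
  tab
}
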