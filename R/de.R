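#' Area under the ROC curve by rank statistics
#'
#' The probability that a random in-group value exceeds a random out-of-group
#' value, ties counted one half — the Mann-Whitney U statistic divided by
#' \code{n_in * n_out}.
#'
#' @param values_in,values_out numeric vectors (both nonempty).
#' @return scalar in [0, 1].
#' @export
compute_auroc <- function(values_in, values_out) {
  n_in <- length(values_in)
  n_out <- length(values_out)
  if (n_in == 0 || n_out == 0) stop("both groups must be nonempty")
  r <- rank(c(values_in, values_out))
  u <- sum(r[seq_len(n_in)]) - n_in * (n_in + 1) / 2
  u / (n_in * n_out)
}

#' One-vs-rest differentially expressed genes
#'
#' For every group: genes expressed (count > 0) in at least \code{min_pct} of
#' the in-group or the out-of-group cells and with a natural-log fold change
#' of at least \code{min_logfc} are tested with a two-sided Wilcoxon rank-sum
#' test on the normalized expression; p-values are Bonferroni-adjusted over
#' the genes tested for that comparison. Only upregulated genes with
#' \code{p_adj <= max_padj} are reported. The log fold change is
#' \code{log(mean(expm1(in)) + 1) - log(mean(expm1(out)) + 1)}.
#'
#' @param norm a \code{"norm_matrix"}.
#' @param grouping a \code{"grouping"} with at least 2 groups.
#' @param min_logfc,min_pct,max_padj thresholds (see above).
#' @return data.frame with columns \code{gene}, \code{group},
#'   \code{avg_logFC}, \code{p}, \code{p_adj}, \code{pct_in}, \code{pct_out},
#'   \code{auroc}, ordered by group then decreasing avg_logFC.
#' @export
find_de_genes <- function(norm, grouping, min_logfc = 0.25, min_pct = 0.1,
                          max_padj = 0.05) {
  stopifnot(inherits(norm, "norm_matrix"), inherits(grouping, "grouping"),
            grouping$k >= 2)
  e <- as.matrix(norm$matrix)               # genes x cells, log scale
  expm1_e <- expm1(e)
  labels <- grouping$labels
  out <- list()
  for (g in sort(unique(labels))) {
    at <- labels == g
    if (sum(at) < 3) {
      warning("group ", g, " has fewer than 3 cells; skipped")
      next
    }
    pct_in <- rowMeans(e[, at, drop = FALSE] > 0)
    pct_out <- rowMeans(e[, !at, drop = FALSE] > 0)
    lfc <- log(rowMeans(expm1_e[, at, drop = FALSE]) + 1) -
      log(rowMeans(expm1_e[, !at, drop = FALSE]) + 1)
    test <- which((pct_in >= min_pct | pct_out >= min_pct) & lfc >= min_logfc)
    if (length(test) == 0) next
    p <- vapply(test, function(i) {
      stats::wilcox.test(e[i, at], e[i, !at], exact = FALSE)$p.value
    }, numeric(1))
    p_adj <- pmin(1, p * length(test))
    keep <- which(p_adj <= max_padj)
    if (length(keep) == 0) next
    auroc <- vapply(test[keep], function(i) compute_auroc(e[i, at], e[i, !at]),
                    numeric(1))
    df <- data.frame(gene = norm$gene_ids[test[keep]], group = g,
                     avg_logFC = lfc[test[keep]], p = p[keep],
                     p_adj = p_adj[keep],
                     pct_in = pct_in[test[keep]], pct_out = pct_out[test[keep]],
                     auroc = auroc)
    out[[length(out) + 1L]] <- df[order(-df$avg_logFC), ]
  }
  if (length(out) == 0)
    return(data.frame(gene = character(0), group = integer(0),
                      avg_logFC = numeric(0), p = numeric(0),
                      p_adj = numeric(0), pct_in = numeric(0),
                      pct_out = numeric(0), auroc = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate per-group relative errors into the final classification error
#'
#' For each split count in \code{nsplit_range}, the group-level error is the
#' group's relative (training) error at that split count times the group's
#' cell fraction; the set-level error is the sum over groups; the final error
#' is the mean of the set-level errors over the split range.
#'
#' @param rel_errors matrix: groups x split counts (columns spanning
#'   \code{nsplit_range[1]..nsplit_range[2]}), entries in [0, 1].
#' @param group_fractions per-group cell fractions, summing to 1.
#' @param nsplit_range inclusive split-count range (used for validation).
#' @return list with \code{set_error_by_nsplit} (named vector) and
#'   \code{final_error}.
#' @export
aggregate_classification_error <- function(rel_errors, group_fractions,
                                           nsplit_range = c(5L, 15L)) {
  nsplits <- nsplit_range[1]:nsplit_range[2]
  stopifnot(ncol(rel_errors) == length(nsplits),
            nrow(rel_errors) == length(group_fractions),
            all(rel_errors >= 0), all(rel_errors <= 1))
  set_err <- colSums(rel_errors * group_fractions)
  names(set_err) <- nsplits
  list(set_error_by_nsplit = set_err, final_error = mean(set_err))
}

#' Decision-tree classification error of a grouping
#'
#' For each group a one-vs-rest CART tree (Gini splits, \pkg{rpart} defaults)
#' is grown on the normalized expression of the union of DE genes. Along the
#' cost-complexity path, the training relative error of the deepest subtree
#' with at most \code{nsplit} splits is read off for every \code{nsplit} in
#' the range (trees that stop early reuse their deepest subtree); the
#' relative-error baseline is the minority-class count at the root, so
#' relative error times group fraction is an absolute error for minority
#' groups. Group, set and final errors are combined by
#' \code{\link{aggregate_classification_error}}.
#'
#' @param norm a \code{"norm_matrix"}.
#' @param grouping a \code{"grouping"}.
#' @param de DE table from \code{\link{find_de_genes}}; must be nonempty.
#' @param nsplit_range inclusive split-count range averaged into the final
#'   error.
#' @return list with \code{per_group} (matrix of relative errors, groups x
#'   nsplit), \code{group_fractions}, \code{set_error_by_nsplit},
#'   \code{final_error}.
#' @export
classification_error <- function(norm, grouping, de,
                                 nsplit_range = c(5L, 15L)) {
  if (is.null(de) || nrow(de) == 0)
    stop("cannot evaluate: no DE genes")
  genes <- unique(de$gene)
  feat <- as.data.frame(t(as.matrix(norm$matrix[match(genes, norm$gene_ids),
                                                , drop = FALSE])))
  colnames(feat) <- make.names(genes)
  nsplits <- nsplit_range[1]:nsplit_range[2]
  groups <- sort(unique(grouping$labels))
  rel <- matrix(1, length(groups), length(nsplits),
                dimnames = list(groups, nsplits))
  frac <- as.numeric(table(factor(grouping$labels, levels = groups))) /
    length(grouping$labels)
  for (i in seq_along(groups)) {
    y <- factor(ifelse(grouping$labels == groups[i], "in", "out"))
    fit <- rpart::rpart(y ~ ., data = cbind(y = y, feat), method = "class",
                        control = rpart::rpart.control(xval = 0))
    cp <- fit$cptable   # columns CP, nsplit, rel error
    rel[i, ] <- vapply(nsplits, function(s) {
      rows <- cp[cp[, "nsplit"] <= s, , drop = FALSE]
      rows[nrow(rows), "rel error"]
    }, numeric(1))
  }
  rel <- pmin(rel, 1)
  agg <- aggregate_classification_error(rel, frac, nsplit_range)
  c(list(per_group = rel, group_fractions = frac), agg)
}

#' Performance summary over candidate sets
#'
#' Per candidate: the median (across groups) count of DE genes above each
#' AUROC cutoff; the median across groups of the mean natural-log fold change
#' of the top 10 (or all, if fewer) DE genes with AUROC > 0.8 per group
#' (also reported on the log2 scale); and the final classification error.
#' The candidate with the lowest final error is marked best (ties: smaller k).
#'
#' @param candidates list of candidate sets, each carrying \code{name},
#'   \code{k}, \code{de} (DE table) and \code{classifier} (result of
#'   \code{\link{classification_error}}).
#' @param cutoffs AUROC cutoffs for the gene counts.
#' @return list with \code{table} (one row per candidate) and \code{best}
#'   (index of the best candidate).
#' @export
summarize_candidates <- function(candidates, cutoffs = c(0.8, 0.85, 0.9)) {
  stopifnot(length(candidates) >= 1)
  rows <- lapply(candidates, function(cand) {
    groups <- sort(unique(cand$grouping$labels))
    de <- cand$de
    counts <- vapply(cutoffs, function(cut) {
      per_group <- vapply(groups, function(g)
        sum(de$group == g & de$auroc > cut), numeric(1))
      stats::median(per_group)
    }, numeric(1))
    top_lfc <- vapply(groups, function(g) {
      d <- de[de$group == g & de$auroc > 0.8, ]
      if (nrow(d) == 0) return(NA_real_)
      mean(utils::head(sort(d$avg_logFC, decreasing = TRUE), 10))
    }, numeric(1))
    med_lfc <- stats::median(top_lfc, na.rm = TRUE)
    df <- data.frame(name = cand$name, nPC = cand$nPC, k = cand$k,
                     gap_increase = cand$gap_increase,
                     median_top10_avg_logFC = med_lfc,
                     median_top10_avg_log2FC = med_lfc / log(2),
                     classification_error = cand$classifier$final_error)
    for (j in seq_along(cutoffs))
      df[[sprintf("n_de_auroc_gt_%g", cutoffs[j])]] <- counts[j]
    df
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best <- order(tab$classification_error, tab$k)[1]
  tab$is_best <- seq_len(nrow(tab)) == best
  list(table = tab, best = best)
}
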