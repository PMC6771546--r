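#' Build a multi-layer cell ontology by recursive sweeps
#'
#' Runs \code{\link{ikap}} on all cells, then re-runs it inside targeted
#' groups of the chosen candidate (by default the largest group at each
#' level; \code{targets = "all"} expands every group) down to
#' \code{max_depth}. Each recursion is a fresh run on the subset: variable
#' genes, scaling, PCA and search bounds are recomputed within the subset,
#' but cells are not re-filtered (they already passed QC). Groups with fewer
#' than \code{config$min_cells_recurse} cells become leaves.
#'
#' @param x input accepted by \code{\link{ikap}}.
#' @param config an \code{\link{ikap_config}}.
#' @param max_depth recursion depth below the root (default 2).
#' @param targets \code{"largest"} (default) or \code{"all"}.
#' @param chosen optional named list mapping node paths (e.g. \code{"root"},
#'   \code{"root/group2"}) to a candidate index or name, overriding the best
#'   set at that node.
#' @param filter whether to filter cells at the root.
#' @return an object of class \code{"ikap_ontology"} wrapping the node tree;
#'   each node carries \code{name}, \code{cell_ids}, \code{result} (an
#'   \code{"ikap"} or NULL for leaves), \code{chosen_candidate} and
#'   \code{children} (named by \code{"group<g>"}).
#' @export
build_ontology <- function(x, config = ikap_config(), max_depth = 2L,
                           targets = c("largest", "all"), chosen = NULL,
                           filter = TRUE) {
  targets <- match.arg(targets)
  stopifnot(max_depth >= 0)
  raw <- if (inherits(x, "raw_counts")) x
    else if (is.character(x)) read_counts(x)
    else raw_counts(x)
  root <- .ontology_node(raw, config, max_depth, targets, chosen,
                         path = "root", filter = filter)
  structure(list(root = root, config = config, max_depth = max_depth,
                 targets = targets),
            class = "ikap_ontology")
}

.ontology_node <- function(raw, config, depth, targets, chosen, path,
                           filter = FALSE) {
  res <- ikap(raw, config = config, filter = filter)
  pick <- if (!is.null(chosen) && !is.null(chosen[[path]]))
    .resolve_candidate(res, chosen[[path]]) else res$best
  node <- list(name = path, cell_ids = res$cell_ids, result = res,
               chosen_candidate = pick, children = list())
  if (depth == 0) return(node)
  labels <- res$candidates[[pick]]$grouping$labels
  sizes <- table(labels)
  groups <- if (targets == "largest") {
    as.integer(names(sizes)[which.max(sizes)])
  } else {
    as.integer(names(sizes))
  }
  for (g in groups) {
    child_name <- paste0("group", g)
    at <- labels == g
    if (sum(at) < config$min_cells_recurse) {
      message(path, "/", child_name, ": ", sum(at),
              " cells, below the recursion minimum; leaf")
      next
    }
    sub_raw <- raw_counts(res$raw$matrix[, at, drop = FALSE],
                          res$raw$gene_ids, res$raw$cell_ids[at],
                          res$raw$mito_pattern)
    node$children[[child_name]] <- .ontology_node(
      sub_raw, config, depth - 1L, targets, chosen,
      path = paste0(path, "/", child_name), filter = FALSE)
  }
  node
}

#' @export
print.ikap_ontology <- function(x, ...) {
  rec <- function(node, indent) {
    tab <- node$result$summary$table
    cat(sprintf("%s%s: %d cells, %s (k=%d)\n",
                strrep("  ", indent), node$name, length(node$cell_ids),
                tab$name[node$chosen_candidate],
                tab$k[node$chosen_candidate]))
    for (ch in node$children) rec(ch, indent + 1)
  }
  cat("cell ontology (depth ", x$max_depth, "):\n", sep = "")
  rec(x$root, 0)
  invisible(x)
}

#' Plain-list view of an ontology (for JSON serialization)
#'
#' @param x an \code{"ikap_ontology"}.
#' @return nested list with \code{name}, \code{n_cells}, \code{candidate},
#'   \code{children}.
#' @export
as_ontology_list <- function(x) {
  rec <- function(node) {
    tab <- node$result$summary$table
    list(name = node$name,
         n_cells = length(node$cell_ids),
         candidate = tab$name[node$chosen_candidate],
         k = tab$k[node$chosen_candidate],
         children = unname(lapply(node$children, rec)))
  }
  rec(x$root)
}

#' Leaf cell sets of an ontology
#'
#' Per leaf group of the tree (groups never recursed into, plus all groups of
#' terminal nodes), the cell ids it contains. The union over leaves equals
#' the root cell set and leaves are pairwise disjoint.
#'
#' @param x an \code{"ikap_ontology"}.
#' @return named list of character vectors of cell ids.
#' @export
ontology_leaves <- function(x) {
  out <- list()
  rec <- function(node) {
    labels <- node$result$candidates[[node$chosen_candidate]]$grouping$labels
    for (g in sort(unique(labels))) {
      child <- node$children[[paste0("group", g)]]
      if (is.null(child)) {
        out[[paste0(node$name, "/group", g)]] <<-
          node$cell_ids[labels == g]
      } else {
        rec(child)
      }
    }
  }
  rec(x$root)
  out
}
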