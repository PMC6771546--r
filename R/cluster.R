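#' Graph-based clustering in PC space
#'
#' Builds a shared-nearest-neighbor (SNN) graph on the top-\code{nPC}
#' coordinates (k-nearest neighbors, Jaccard-weighted shared-neighbor edges,
#' edges below \code{prune} removed) and partitions it by modularity-maximizing
#' Leiden community detection at the given resolution. Deterministic for a
#' fixed seed.
#'
#' @param pc a \code{"pc_embedding"}.
#' @param nPC number of leading components to use.
#' @param resolution modularity resolution; higher values give more groups.
#' @param seed integer RNG seed.
#' @param knn neighbor count (reduced with a warning if there are fewer cells).
#' @param prune Jaccard threshold below which SNN edges are dropped.
#' @return an object of class \code{"grouping"}: list with \code{labels}
#'   (integer 0..k-1 per cell, groups ordered by decreasing size), \code{k},
#'   \code{nPC}, \code{resolution}.
#' @export
cluster_cells <- function(pc, nPC, resolution, seed = 0L,
                          knn = 20L, prune = 1 / 15) {
  stopifnot(inherits(pc, "pc_embedding"), nPC >= 1, nPC <= ncol(pc$scores),
            resolution > 0)
  x <- pc$scores[, seq_len(nPC), drop = FALSE]
  n <- nrow(x)
  if (knn >= n) {
    warning("fewer cells (", n, ") than neighbor count (", knn,
            "); using ", n - 1L, " neighbors")
    knn <- n - 1L
  }
  adj <- .knn_sets(x, knn)                      # n x n sparse 0/1, self included
  inter <- Matrix::tcrossprod(adj)              # shared-neighbor counts
  sz <- knn + 1
  jac <- inter
  jac@x <- jac@x / (2 * sz - jac@x)             # |A∩B| / |A∪B|
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  memb <- if (igraph::ecount(g) == 0) {
    rep(1L, n)  # no edges survive pruning: a single (degenerate) community
  } else {
    set.seed(seed)
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = resolution,
      weights = igraph::E(g)$weight, n_iterations = 5))
  }
  .as_grouping(memb, nPC = nPC, resolution = resolution)
}

# sparse membership matrix of k-nearest-neighbor sets (self included)
.knn_sets <- function(x, knn) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  idx <- vapply(seq_len(n),
                function(i) order(d[i, ])[seq_len(knn + 1)],
                integer(knn + 1))
  Matrix::sparseMatrix(i = rep(seq_len(n), each = knn + 1),
                       j = as.integer(idx), x = 1, dims = c(n, n))
}

# canonical grouping: labels 0..k-1, ordered by decreasing group size
# (ties by first occurrence)
.as_grouping <- function(memb, nPC = NA_integer_, resolution = NA_real_) {
  memb <- as.integer(memb)
  tab <- table(memb)
  ord <- names(tab)[order(-as.integer(tab),
                          match(names(tab), as.character(memb)))]
  labels <- match(as.character(memb), ord) - 1L
  structure(list(labels = labels, k = length(ord),
                 nPC = as.integer(nPC), resolution = resolution),
            class = "grouping")
}

#' @export
print.grouping <- function(x, ...) {
  cat(sprintf("grouping: %d cells in %d group(s) [nPC=%s, r=%s]\n",
              length(x$labels), x$k,
              ifelse(is.na(x$nPC), "-", x$nPC),
              ifelse(is.na(x$resolution), "-", format(x$resolution))))
  print(table(group = x$labels))
  invisible(x)
}

#' Elbow rule for the minimum number of components
#'
#' Returns the first component index i such that the relative decrease in
#' explained standard deviation, \code{(sdev[j] - sdev[j+1]) / sdev[j]}, is
#' below 10\% for every following component j >= i. If even the last pair
#' violates the rule, \code{length(sdev) - 1} is returned with a warning.
#'
#' @param sdev nonincreasing positive vector of component standard deviations.
#' @param drop_tol maximal relative drop considered flat (default 0.10).
#' @return integer index (1-based).
#' @export
choose_npc_min <- function(sdev, drop_tol = 0.10) {
  L <- length(sdev)
  stopifnot(L >= 2)
  if (any(sdev <= 0)) stop("sdev must be positive")
  if (any(diff(sdev) > 1e-12)) stop("sdev must be nonincreasing")
  drops <- (sdev[-L] - sdev[-1]) / sdev[-L]
  viol <- which(drops >= drop_tol)
  if (length(viol) == 0) return(1L)
  last <- max(viol)
  if (last >= L - 1L) {
    warning("explained-sdev curve never flattens; using ", L - 1L,
            " components")
    return(L - 1L)
  }
  as.integer(last + 1L)
}

# round half away from zero (k_max is a count; base round() is banker's)
.round_half_up <- function(x) floor(x + 0.5)

#' Determine the (nPC, k) search space
#'
#' \code{nPC_min} comes from the elbow rule on the explained standard
#' deviations; \code{nPC_max = nPC_min + npc_span}, capped at the number of
#' computed components (with a warning); \code{k_max} is the half-up-rounded
#' mean of the group counts obtained by clustering at resolution
#' \code{r_ini} with \code{nPC_min} and with \code{nPC_max} components,
#' floored at 2.
#'
#' @param pc a \code{"pc_embedding"}.
#' @param config an \code{\link{ikap_config}}.
#' @return list with \code{nPC_min}, \code{nPC_max}, \code{k_max}.
#' @export
sweep_bounds <- function(pc, config = ikap_config()) {
  P <- ncol(pc$scores)
  npc_min <- choose_npc_min(pc$sdev)
  npc_max <- npc_min + config$npc_span
  if (npc_max > P) {
    warning("nPC_max capped at the ", P, " computed components")
    npc_max <- P
  }
  k_lo <- cluster_cells(pc, npc_min, config$r_ini,
                        seed = .sub_seed(config$seed, npc_min, 999),
                        knn = config$knn, prune = config$snn_prune)$k
  k_hi <- cluster_cells(pc, npc_max, config$r_ini,
                        seed = .sub_seed(config$seed, npc_max, 999),
                        knn = config$knn, prune = config$snn_prune)$k
  k_max <- max(2L, as.integer(.round_half_up(mean(c(k_lo, k_hi)))))
  list(nPC_min = as.integer(npc_min), nPC_max = as.integer(npc_max),
       k_max = k_max)
}

#' Initial fine partition for one nPC
#'
#' Clusters at resolution \code{r_start} and raises the resolution by
#' \code{r_step} until the partition has at least \code{k_max} groups; errors
#' if the resolution cap is exceeded first.
#'
#' @param pc a \code{"pc_embedding"}.
#' @param nPC number of leading components.
#' @param k_max required minimum number of groups.
#' @param config an \code{\link{ikap_config}}.
#' @return a \code{"grouping"} with \code{k >= k_max}; its \code{resolution}
#'   records the r used.
#' @export
initial_partition <- function(pc, nPC, k_max, config = ikap_config()) {
  stopifnot(k_max >= 2)
  r <- config$r_start
  repeat {
    if (r > config$r_cap + 1e-9)
      stop("resolution cap ", config$r_cap, " reached with fewer than ",
           k_max, " groups; consider a smaller k_max")
    g <- cluster_cells(pc, nPC, r, seed = .sub_seed(config$seed, nPC, r * 10),
                       knn = config$knn, prune = config$snn_prune)
    if (g$k >= k_max) return(g)
    r <- r + config$r_step
  }
}
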