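#' Nested partitions by iterative nearest-centroid merging
#'
#' Starting from a fine partition, the two groups whose centroids (unweighted
#' means of member-cell coordinates in the top-\code{nPC} space) are closest
#' in Euclidean distance are united, centroids are recomputed, and the process
#' repeats down to a single group. Distance ties are broken by the smallest
#' (group_a, group_b) id pair. The partitions for k = 1..k_max are retained.
#'
#' @param pc a \code{"pc_embedding"}.
#' @param nPC number of leading components.
#' @param initial a \code{"grouping"} with at least \code{k_max} groups.
#' @param k_max largest k to retain.
#' @return an object of class \code{"grouping_series"}: list with \code{nPC},
#'   \code{k_ini} (the initial group count), \code{partitions} (list indexed
#'   by k, \code{partitions[[k]]} having exactly k groups), and
#'   \code{merge_trace} (data.frame of the united id pairs and their centroid
#'   distance, in merge order).
#' @export
merge_series <- function(pc, nPC, initial, k_max) {
  stopifnot(inherits(initial, "grouping"))
  if (initial$k < k_max)
    stop("initial partition has ", initial$k, " groups, fewer than k_max = ",
         k_max)
  x <- pc$scores[, seq_len(nPC), drop = FALSE]
  lab <- initial$labels                       # running 0-based ids
  ids <- sort(unique(lab))
  cent <- do.call(rbind, lapply(ids, function(g)
    colMeans(x[lab == g, , drop = FALSE])))
  sizes <- as.integer(table(factor(lab, levels = ids)))
  rownames(cent) <- ids
  partitions <- vector("list", k_max)
  trace <- list()
  k <- length(ids)
  if (k <= k_max) partitions[[k]] <- .as_grouping(lab, nPC = nPC)
  while (k > 1) {
    d <- as.matrix(stats::dist(cent))
    d[upper.tri(d, diag = TRUE)] <- Inf
    # min distance; ties -> smallest (a, b) id pair
    flat <- which(d == min(d), arr.ind = TRUE)
    pair_ids <- cbind(as.integer(rownames(cent)[flat[, 2]]),
                      as.integer(rownames(cent)[flat[, 1]]))  # a < b by id? not yet
    pair_ids <- t(apply(pair_ids, 1, sort))
    pick <- order(pair_ids[, 1], pair_ids[, 2])[1]
    a <- pair_ids[pick, 1]; b <- pair_ids[pick, 2]
    dmin <- min(d)
    ia <- match(as.character(a), rownames(cent))
    ib <- match(as.character(b), rownames(cent))
    # recompute the merged centroid from all member cells
    cent[ia, ] <- (cent[ia, ] * sizes[ia] + cent[ib, ] * sizes[ib]) /
      (sizes[ia] + sizes[ib])
    sizes[ia] <- sizes[ia] + sizes[ib]
    cent <- cent[-ib, , drop = FALSE]
    sizes <- sizes[-ib]
    lab[lab == b] <- a
    k <- k - 1L
    trace[[length(trace) + 1L]] <- data.frame(group_a = a, group_b = b,
                                              centroid_distance = dmin)
    if (k <= k_max) partitions[[k]] <- .as_grouping(lab, nPC = nPC)
  }
  structure(list(nPC = as.integer(nPC), k_ini = initial$k,
                 partitions = partitions,
                 merge_trace = do.call(rbind, trace)),
            class = "grouping_series")
}

#' Within-group dispersion
#'
#' \code{W = sum_r D_r / (2 n_r)} where \code{D_r} is the sum of Euclidean
#' distances over all ordered within-group pairs and \code{n_r} the group
#' size (the pooled within-cluster dispersion of the gap statistic).
#' Singleton groups contribute zero. With
#' \code{normalization = "raw_sum"} the plain sum of ordered pairwise
#' distances is returned instead.
#'
#' @param pc a \code{"pc_embedding"}.
#' @param nPC number of leading components.
#' @param grouping a \code{"grouping"}.
#' @param normalization \code{"normalized"} (default) or \code{"raw_sum"}.
#' @return scalar W.
#' @export
within_dispersion <- function(pc, nPC, grouping,
                              normalization = c("normalized", "raw_sum")) {
  stopifnot(inherits(grouping, "grouping"))
  x <- pc$scores[, seq_len(nPC), drop = FALSE]
  .dispersion(x, grouping$labels, match.arg(normalization))
}

.dispersion <- function(x, labels, normalization = "normalized") {
  w <- 0
  for (g in unique(labels)) {
    at <- labels == g
    n_r <- sum(at)
    if (n_r < 2) next
    d_r <- 2 * sum(stats::dist(x[at, , drop = FALSE]))  # ordered pairs
    w <- w + if (normalization == "normalized") d_r / (2 * n_r) else d_r
  }
  w
}

#' Gap statistic of a grouping
#'
#' \code{Gap = mean_b log W*_b - log W_obs}: the observed log within-group
#' dispersion is compared with its expectation under \code{B} reference draws
#' of the same number of cells sampled uniformly in the axis-aligned bounding
#' box of the observed top-\code{nPC} coordinates. Each reference draw is
#' partitioned into the same number of groups by seeded k-means (10 restarts);
#' with \code{reference = "merge"} the draw goes through the same
#' cluster-and-merge pipeline as the observed data. Reproducible for a fixed
#' seed.
#'
#' The attribute \code{"se"} carries the null standard error of the gap,
#' \code{sd(log W*_b) * sqrt(1 + 1/B)}, accounting for both the Monte-Carlo
#' average and the single observed draw.
#'
#' @param pc a \code{"pc_embedding"}.
#' @param nPC number of leading components.
#' @param grouping a \code{"grouping"} of the cells.
#' @param B number of reference draws.
#' @param seed integer seed for the reference stream.
#' @param normalization passed to \code{\link{within_dispersion}}.
#' @param reference reference-partitioning backend.
#' @param config configuration used when \code{reference = "merge"}.
#' @return scalar gap value with attribute \code{"se"}.
#' @export
gap_statistic <- function(pc, nPC, grouping, B = 100L, seed = 0L,
                          normalization = c("normalized", "raw_sum"),
                          reference = c("kmeans", "merge"),
                          config = ikap_config()) {
  normalization <- match.arg(normalization)
  reference <- match.arg(reference)
  stopifnot(B >= 1)
  x <- pc$scores[, seq_len(nPC), drop = FALSE]
  n <- nrow(x)
  k <- grouping$k
  w_obs <- .dispersion(x, grouping$labels, normalization)
  if (w_obs <= 0 && k < n)
    stop("observed within-group dispersion is zero (duplicate points?)")
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  set.seed(seed)
  log_wb <- numeric(B)
  for (b in seq_len(B)) {
    ref <- matrix(stats::runif(n * ncol(x)), n) *
      rep(hi - lo, each = n) + rep(lo, each = n)
    ref_lab <- if (k == 1) {
      rep(0L, n)
    } else if (reference == "kmeans") {
      stats::kmeans(ref, centers = k, nstart = 10, iter.max = 25)$cluster
    } else {
      ref_pc <- structure(list(scores = ref, sdev = rep(1, ncol(ref)),
                               cell_ids = seq_len(n)),
                          class = "pc_embedding")
      ini <- initial_partition(ref_pc, ncol(ref), k, config)
      merge_series(ref_pc, ncol(ref), ini, k)$partitions[[k]]$labels
    }
    log_wb[b] <- log(.dispersion(ref, ref_lab, normalization))
  }
  gap <- mean(log_wb) - log(w_obs)
  attr(gap, "se") <- stats::sd(log_wb) * sqrt(1 + 1 / B)
  gap
}

#' Gap and gap-increase matrices over the (nPC, k) sweep
#'
#' For every nPC in \code{[nPC_min, nPC_max]}: build the initial fine
#' partition, merge it into nested partitions for k = 1..k_max, compute the
#' gap statistic of each, and tabulate \code{Gap(nPC, k)} and the increase
#' \code{M(nPC, k) = Gap(nPC, k) - Gap(nPC, k - 1)} (undefined, NA, at k = 1).
#'
#' @param pc a \code{"pc_embedding"}.
#' @param bounds list with \code{nPC_min}, \code{nPC_max}, \code{k_max}
#'   (see \code{\link{sweep_bounds}}).
#' @param config an \code{\link{ikap_config}}.
#' @return list with \code{gap} and \code{increase} (matrices with nPC row
#'   names and k column names), \code{B}, \code{seed}, and \code{series}
#'   (named list of \code{"grouping_series"}, one per nPC).
#' @export
gap_increase_matrix <- function(pc, bounds, config = ikap_config()) {
  npcs <- bounds$nPC_min:bounds$nPC_max
  k_max <- bounds$k_max
  gap <- matrix(NA_real_, length(npcs), k_max,
                dimnames = list(npcs, seq_len(k_max)))
  series <- stats::setNames(vector("list", length(npcs)), npcs)
  for (i in seq_along(npcs)) {
    npc <- npcs[i]
    ini <- initial_partition(pc, npc, k_max, config)
    ser <- merge_series(pc, npc, ini, k_max)
    series[[i]] <- ser
    for (k in seq_len(k_max)) {
      gap[i, k] <- gap_statistic(
        pc, npc, ser$partitions[[k]], B = config$gap_B,
        seed = .sub_seed(config$seed, npc, k),
        normalization = config$dispersion_norm,
        reference = config$gap_reference, config = config)
    }
  }
  increase <- gap - cbind(NA_real_, gap[, -k_max, drop = FALSE])
  dimnames(increase) <- dimnames(gap)
  list(gap = gap, increase = increase, B = config$gap_B, seed = config$seed,
       series = series)
}
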