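#' Select candidate (nPC, k) sets from the gap-increase matrix
#'
#' The selection proceeds in four steps: (0) entries at or below
#' \code{mean + sd_mult * sd} (moments over all finite entries of the matrix,
#' sample sd) are filtered out; (1) for every column k the surviving entry
#' with the largest increase is kept (ties: smaller nPC); (2) the kept
#' entries are sorted by increase in descending order (ties: smaller k);
#' (3) the sorted list is scanned greedily, accepting an entry iff both its
#' nPC and its k strictly exceed those of every entry accepted so far (the
#' first entry is always accepted). If the filter removes everything, the
#' single global-maximum entry is returned with a warning.
#'
#' @param gm result of \code{\link{gap_increase_matrix}} (or any list with an
#'   \code{increase} matrix whose dimnames are nPC and k).
#' @param sd_mult multiplier on the standard deviation in the filter.
#' @return data.frame of accepted picks with columns \code{nPC}, \code{k},
#'   \code{gap_increase}, \code{rank}; the filter threshold is attached as
#'   attribute \code{"threshold"}.
#' @export
select_candidates <- function(gm, sd_mult = 1) {
  m <- gm$increase
  vals <- m[is.finite(m)]
  if (length(vals) == 0) stop("gap-increase matrix has no finite entries")
  threshold <- mean(vals) + sd_mult * stats::sd(vals)
  if (is.na(threshold)) threshold <- mean(vals)  # single-entry matrix
  npc_of <- as.integer(rownames(m))
  k_of <- as.integer(colnames(m))
  surv <- which(is.finite(m) & m > threshold, arr.ind = TRUE)
  if (nrow(surv) == 0) {
    warning("no gap increase exceeds the filter threshold; ",
            "falling back to the global maximum")
    best <- which(m == max(vals), arr.ind = TRUE)
    best <- best[order(npc_of[best[, 1]], k_of[best[, 2]]), , drop = FALSE]
    picks <- data.frame(nPC = npc_of[best[1, 1]], k = k_of[best[1, 2]],
                        gap_increase = max(vals))
  } else {
    # step 1: column maxima (ties -> smaller nPC)
    cols <- split(seq_len(nrow(surv)), k_of[surv[, 2]])
    picks <- do.call(rbind, lapply(cols, function(rows) {
      v <- m[surv[rows, , drop = FALSE]]
      at <- rows[v == max(v)]
      at <- at[order(npc_of[surv[at, 1]])][1]
      data.frame(nPC = npc_of[surv[at, 1]], k = k_of[surv[at, 2]],
                 gap_increase = m[surv[at, , drop = FALSE]])
    }))
    # step 2: sort by increase descending (ties -> smaller k)
    picks <- picks[order(-picks$gap_increase, picks$k), , drop = FALSE]
  }
  out <- greedy_candidate_filter(picks)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  if (nrow(out) > 4)
    warning("more than 4 candidate sets (", nrow(out),
            "); this is unusually many")
  out
}

#' Greedy acceptance over a sorted candidate list
#'
#' Scans a list of (nPC, k) entries, already sorted by gap increase in
#' descending order, and accepts an entry iff its nPC is greater than every
#' accepted nPC and its k is greater than every accepted k; the first entry
#' is always accepted. This is the acceptance rule behind
#' \code{\link{select_candidates}}, exposed so that a pre-built sorted list
#' can be pushed through it directly.
#'
#' @param picks data.frame with columns \code{nPC} and \code{k} (and,
#'   optionally, \code{gap_increase}), sorted by decreasing gap increase.
#' @return the accepted subset, in acceptance order; nPC and k are strictly
#'   increasing along the result.
#' @export
greedy_candidate_filter <- function(picks) {
  stopifnot(all(c("nPC", "k") %in% names(picks)))
  keep <- logical(nrow(picks))
  max_npc <- -Inf
  max_k <- -Inf
  for (i in seq_len(nrow(picks))) {
    if (picks$nPC[i] > max_npc && picks$k[i] > max_k) {
      keep[i] <- TRUE
      max_npc <- picks$nPC[i]
      max_k <- picks$k[i]
    }
  }
  out <- picks[keep, , drop = FALSE]
  stopifnot(all(diff(out$nPC) > 0), all(diff(out$k) > 0))
  out
}

#' Attach partitions to candidate picks
#'
#' @param picks data.frame from \code{\link{select_candidates}}.
#' @param series named list of \code{"grouping_series"} keyed by nPC (from
#'   \code{\link{gap_increase_matrix}}).
#' @return list of candidate sets, each a list with \code{name}
#'   (\code{"PC<nPC>K<k>"}), \code{nPC}, \code{k}, \code{gap_increase} and
#'   \code{grouping} (a \code{"grouping"} with exactly k groups).
#' @export
materialize_candidates <- function(picks, series) {
  lapply(seq_len(nrow(picks)), function(i) {
    npc <- picks$nPC[i]
    k <- picks$k[i]
    ser <- series[[as.character(npc)]]
    if (is.null(ser)) stop("no grouping series for nPC = ", npc)
    grouping <- ser$partitions[[k]]
    stopifnot(grouping$k == k)
    list(name = sprintf("PC%dK%d", npc, k), nPC = npc, k = k,
         gap_increase = picks$gap_increase[i], grouping = grouping)
  })
}
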