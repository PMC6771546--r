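# shared fixtures: all built in code, no files on disk

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# wrap a coordinate matrix as a PC embedding
make_pc <- function(scores, sdev = NULL) {
  scores <- as.matrix(scores)
  if (is.null(sdev)) sdev <- sort(apply(scores, 2, sd), decreasing = TRUE)
  structure(list(scores = scores, sdev = sdev,
                 genes_used = character(0),
                 cell_ids = paste0("c", seq_len(nrow(scores)))),
            class = "pc_embedding")
}

# wrap a label vector as a grouping
make_grouping <- function(labels, nPC = NA_integer_) {
  labels <- as.integer(labels)
  structure(list(labels = labels, k = length(unique(labels)),
                 nPC = nPC, resolution = NA_real_),
            class = "grouping")
}

# Gaussian blobs in d dimensions: centers (rows) and per-blob sizes
make_blobs <- function(centers, n_per, noise_sd = 1, seed = 1) {
  set.seed(seed)
  centers <- as.matrix(centers)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * ncol(centers), sd = noise_sd), n_per) +
      rep(centers[i, ], each = n_per)
  }))
  list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# tiny count matrix with one clean marker gene per group plus flat background
make_marker_counts <- function(n_groups = 3, cells_per = 30, n_noise = 20,
                               marker_value = 5, seed = 1) {
  set.seed(seed)
  n <- n_groups * cells_per
  labels <- rep(seq_len(n_groups) - 1L, each = cells_per)
  m <- matrix(rpois(n_noise * n, 1), n_noise, n)
  for (g in seq_len(n_groups)) {
    row <- ifelse(labels == g - 1L, marker_value, 0)
    m <- rbind(m, row)
  }
  rownames(m) <- c(sprintf("Noise%02d", seq_len(n_noise)),
                   sprintf("Marker%d", seq_len(n_groups)))
  colnames(m) <- sprintf("cell%03d", seq_len(n))
  list(counts = raw_counts(m), labels = labels)
}

# scaled-down sweep configuration used by the simulation-heavy tests
desk_config <- function(seed = 0L, ...) {
  ikap_config(gap_B = 25L, npc_span = 8L, n_pcs = 30L, seed = seed, ...)
}
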