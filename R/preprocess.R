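#' Filter low-quality cells
#'
#' Keeps cells expressing at least \code{min_genes} genes (count > 0) and with
#' a mitochondrial UMI fraction of at most \code{max_mito_frac}. Both bounds
#' are inclusive: a cell with exactly \code{min_genes} genes or exactly the
#' maximum mitochondrial fraction is kept. Mitochondrial genes are identified
#' by a case-insensitive prefix match on the gene symbol
#' (\code{raw$mito_pattern}, default \code{"MT-"}).
#'
#' @param raw a \code{"raw_counts"} object.
#' @param min_genes minimum number of detected genes per cell.
#' @param max_mito_frac maximum mitochondrial UMI fraction.
#' @return the filtered \code{"raw_counts"} object, with attribute
#'   \code{"kept_mask"} (logical over the input cells).
#' @export
filter_cells <- function(raw, min_genes = 200L, max_mito_frac = 0.05) {
  stopifnot(inherits(raw, "raw_counts"))
  n_genes <- Matrix::colSums(raw$matrix > 0)
  mf <- mito_fraction(raw)
  keep <- (n_genes >= min_genes) & (mf <= max_mito_frac)
  if (!any(keep)) {
    stop(sprintf(
      "all %d cells removed (%d below %d detected genes, %d above mito fraction %.3g)",
      length(keep), sum(n_genes < min_genes), min_genes,
      sum(mf > max_mito_frac), max_mito_frac))
  }
  out <- raw_counts(raw$matrix[, keep, drop = FALSE],
                    raw$gene_ids, raw$cell_ids[keep], raw$mito_pattern)
  attr(out, "kept_mask") <- keep
  out
}

#' Per-cell mitochondrial UMI fraction
#'
#' @param raw a \code{"raw_counts"} object.
#' @return numeric vector over cells; zero everywhere when no gene matches the
#'   mitochondrial prefix.
#' @export
mito_fraction <- function(raw) {
  is_mito <- startsWith(toupper(raw$gene_ids), toupper(raw$mito_pattern))
  tot <- Matrix::colSums(raw$matrix)
  mito <- if (any(is_mito))
    Matrix::colSums(raw$matrix[is_mito, , drop = FALSE]) else rep(0, ncol(raw$matrix))
  ifelse(tot > 0, mito / tot, 0)
}

#' Log-normalize UMI counts
#'
#' Per cell, counts are scaled to \code{scale_factor} total and
#' log-transformed: \code{ln(1 + count / total * scale_factor)}. Zeros map to
#' exactly zero, so sparsity is preserved.
#'
#' @param raw a \code{"raw_counts"} object; every cell must have a positive
#'   total (filter first).
#' @param scale_factor library-size target (default 1e4).
#' @return an object of class \code{"norm_matrix"}: list with \code{matrix}
#'   (sparse genes x cells log-normalized values), \code{total_umi},
#'   \code{mito_frac}, \code{gene_ids}, \code{cell_ids}.
#' @export
normalize_counts <- function(raw, scale_factor = 1e4) {
  stopifnot(inherits(raw, "raw_counts"))
  tot <- Matrix::colSums(raw$matrix)
  if (any(tot <= 0))
    stop(sum(tot <= 0), " cell(s) with zero total UMI; filter cells first")
  m <- raw$matrix
  # scale columns then log1p; operates on non-zero slots only
  m@x <- log1p(m@x / rep.int(tot, diff(m@p)) * scale_factor)
  structure(list(matrix = m, total_umi = as.numeric(tot),
                 mito_frac = mito_fraction(raw),
                 gene_ids = raw$gene_ids, cell_ids = raw$cell_ids),
            class = "norm_matrix")
}

#' Select highly variable genes
#'
#' Mean/dispersion-bin selection: per gene, the mean expression
#' \code{log1p(mean(expm1(normalized)))} and the dispersion
#' \code{log(variance / mean)} of the de-logged values are computed; genes
#' are binned into \code{n_bins} equal-width bins of mean, the dispersion is
#' z-scored within each bin, and genes inside the mean window with a
#' dispersion z-score of at least \code{min_dispersion_z} are kept.
#'
#' @param norm a \code{"norm_matrix"}.
#' @param n_bins number of equal-width mean bins.
#' @param min_mean,max_mean open window on the log-scale mean (strict
#'   inequalities).
#' @param min_dispersion_z minimum within-bin dispersion z-score.
#' @return character vector of selected gene ids (a subset of
#'   \code{norm$gene_ids}, no duplicates).
#' @export
select_variable_genes <- function(norm, n_bins = 20L, min_mean = 0.1,
                                  max_mean = 8, min_dispersion_z = 1) {
  stopifnot(inherits(norm, "norm_matrix"))
  e <- norm$matrix
  e@x <- expm1(e@x)
  n <- ncol(e)
  mu_raw <- Matrix::rowMeans(e)
  ex2 <- Matrix::rowMeans(e^2)
  v <- (ex2 - mu_raw^2) * n / max(n - 1, 1)
  mu <- log1p(mu_raw)
  disp <- ifelse(mu_raw > 0 & v > 0, log(v / mu_raw), 0)
  # equal-width bins over the observed mean range
  brk <- seq(min(mu), max(mu), length.out = n_bins + 1)
  brk[1] <- brk[1] - 1e-9
  brk[length(brk)] <- brk[length(brk)] + 1e-9
  bin <- cut(mu, breaks = brk, labels = FALSE)
  z <- disp
  for (b in unique(bin)) {
    at <- bin == b
    m_b <- mean(disp[at])
    s_b <- stats::sd(disp[at])
    z[at] <- if (is.na(s_b) || s_b == 0) 0 else (disp[at] - m_b) / s_b
  }
  keep <- mu > min_mean & mu < max_mean & z >= min_dispersion_z
  genes <- norm$gene_ids[keep]
  if (length(genes) < 2)
    stop("fewer than 2 variable genes survive the cutoffs")
  genes
}

#' Regress out covariates and scale
#'
#' Per gene, ordinary least squares of the normalized expression on the
#' covariates (plus intercept); residuals are standardized to unit sample
#' (n-1) variance and clipped to \code{[-clip, clip]}. With no covariates this
#' is a per-gene z-score. Constant genes scale to all zeros. Rank-deficient
#' covariate matrices are handled by pivoted QR (redundant columns dropped,
#' with a warning).
#'
#' @param norm a \code{"norm_matrix"}.
#' @param covariates per-cell numeric matrix / data.frame (rows align with
#'   cells), or NULL.
#' @param clip symmetric clipping bound on the scaled values.
#' @param genes optional subset of gene ids to scale (typically the variable
#'   genes); default all.
#' @return an object of class \code{"scaled_matrix"}: list with \code{matrix}
#'   (dense genes x cells), \code{gene_ids}, \code{cell_ids}.
#' @export
regress_and_scale <- function(norm, covariates = NULL, clip = 10,
                              genes = NULL) {
  stopifnot(inherits(norm, "norm_matrix"))
  if (is.null(genes)) genes <- norm$gene_ids
  idx <- match(genes, norm$gene_ids)
  if (anyNA(idx)) stop("unknown gene ids in `genes`")
  em <- t(as.matrix(norm$matrix[idx, , drop = FALSE]))  # cells x genes
  n <- nrow(em)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    x <- cbind(`(Intercept)` = 1, as.matrix(covariates))
    if (nrow(x) != n) stop("covariate rows do not align with cells")
    qx <- qr(x)
    if (qx$rank < ncol(x))
      warning("covariates are rank-deficient; ",
              ncol(x) - qx$rank, " redundant column(s) dropped")
    res <- qr.resid(qx, em)
  } else {
    res <- sweep(em, 2, colMeans(em))
  }
  res <- sweep(res, 2, colMeans(res))  # exact zero mean per gene
  sds <- apply(res, 2, stats::sd)
  # genes that are constant, or fitted exactly by the covariates (residual
  # variance at numerical-noise level), scale to all zeros
  orig_sds <- apply(em, 2, stats::sd)
  sds[sds == 0 | !is.finite(sds) | sds <= 1e-10 * pmax(orig_sds, 1)] <- Inf
  res <- sweep(res, 2, sds, "/")
  res[res > clip] <- clip
  res[res < -clip] <- -clip
  structure(list(matrix = t(res), gene_ids = genes, cell_ids = norm$cell_ids),
            class = "scaled_matrix")
}

#' Principal components of the scaled matrix
#'
#' Cells are projected on the top components of the gene-standardized matrix.
#' Component standard deviations derive from the singular values
#' (\code{d / sqrt(n - 1)}) and are nonincreasing. The sign of each component
#' is fixed so that its largest-magnitude gene loading is positive. If the
#' matrix is (numerically) all-zero, a zero embedding is returned with a
#' warning.
#'
#' @param scaled a \code{"scaled_matrix"}.
#' @param n_components number of components, at most
#'   \code{min(genes, cells) - 1}.
#' @return an object of class \code{"pc_embedding"}: list with \code{scores}
#'   (cells x n_components), \code{sdev}, \code{genes_used}, \code{cell_ids}.
#' @export
compute_pca <- function(scaled, n_components) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  x <- t(scaled$matrix)                       # cells x genes
  n <- nrow(x)
  p_max <- min(dim(x)) - 1L
  if (n_components > p_max)
    stop("n_components (", n_components, ") exceeds min(genes, cells) - 1 = ",
         p_max)
  x <- sweep(x, 2, colMeans(x))
  if (max(abs(x)) < 1e-12) {
    warning("scaled matrix is zero (identical cells); returning zero embedding")
    return(structure(list(scores = matrix(0, n, n_components),
                          sdev = rep(0, n_components),
                          genes_used = scaled$gene_ids,
                          cell_ids = scaled$cell_ids),
                     class = "pc_embedding"))
  }
  sv <- svd(x, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(n_components)) {
    ld <- sv$v[, j]
    if (ld[which.max(abs(ld))] < 0) {
      sv$v[, j] <- -ld
      sv$u[, j] <- -sv$u[, j]
    }
  }
  structure(list(scores = sv$u %*% diag(d, n_components),
                 sdev = d / sqrt(n - 1),
                 genes_used = scaled$gene_ids,
                 cell_ids = scaled$cell_ids),
            class = "pc_embedding")
}

#' @export
print.pc_embedding <- function(x, ...) {
  cat(sprintf("PC embedding: %d cells x %d components (sdev %.3g .. %.3g)\n",
              nrow(x$scores), ncol(x$scores), x$sdev[1],
              x$sdev[length(x$sdev)]))
  invisible(x)
}
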