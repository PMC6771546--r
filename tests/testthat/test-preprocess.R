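make_qc_counts <- function() {
  # 300 genes incl. 2 mito; cells engineered around the filter boundaries
  n_genes <- 300
  gene_ids <- c("MT-1", "MT-2", sprintf("G%03d", seq_len(n_genes - 2)))
  cells <- list(
    exactly200 = c(0, 0, rep(1, 200), rep(0, 98)),
    only199    = c(0, 0, rep(1, 199), rep(0, 99)),
    mito5pct   = c(12, 0, rep(1, 228), rep(0, 70)),   # 12 / 240 = 5% exactly
    mito6pct   = c(13, 0, rep(1, 228), rep(0, 70)),   # 13 / 241 > 5%
    rich       = c(1, 1, rep(2, 298))
  )
  m <- do.call(cbind, cells)
  rownames(m) <- gene_ids
  raw_counts(m)
}

test_that("cell filter bounds are inclusive on genes and mito fraction", {
  rc <- make_qc_counts()
  mf <- mito_fraction(rc)
  expect_equal(mf[["mito5pct"]], 0.05)
  kept <- filter_cells(rc)
  expect_true("exactly200" %in% kept$cell_ids)
  expect_false("only199" %in% kept$cell_ids)
  expect_true("mito5pct" %in% kept$cell_ids)
  expect_false("mito6pct" %in% kept$cell_ids)
  # idempotent
  again <- filter_cells(kept)
  expect_identical(again$cell_ids, kept$cell_ids)
})

test_that("filtering errors out when nothing survives, with failure counts", {
  m <- matrix(1, 10, 3, dimnames = list(sprintf("G%d", 1:10), c("a", "b", "c")))
  expect_error(filter_cells(raw_counts(m)), "3 below 200")
})

test_that("matrices without mitochondrial genes get zero mito fractions", {
  m <- matrix(1, 250, 2,
              dimnames = list(sprintf("G%03d", 1:250), c("a", "b")))
  rc <- raw_counts(m)
  expect_equal(mito_fraction(rc), c(a = 0, b = 0))
  expect_equal(ncol(filter_cells(rc)$matrix), 2)
})

test_that("log-normalization follows the closed form and is scale-free", {
  m <- matrix(0, 3, 1, dimnames = list(c("g1", "g2", "g3"), "c1"))
  m[1, 1] <- 10
  m[2, 1] <- 9990
  norm <- normalize_counts(raw_counts(m))
  expect_equal(norm$matrix[1, 1], log(1 + 10), tolerance = 1e-12)
  expect_equal(norm$matrix[3, 1], 0)
  # doubling a cell's counts leaves its normalized vector unchanged
  m2 <- cbind(c1 = m[, 1], c2 = 2 * m[, 1])
  norm2 <- normalize_counts(raw_counts(m2))
  expect_equal(norm2$matrix[, 1], norm2$matrix[, 2], tolerance = 1e-12)
  expect_error(normalize_counts(raw_counts(m * 0)), "zero total")
})

test_that("scaling without covariates is a sample-sd z-score, clipped", {
  norm <- structure(list(
    matrix = Matrix::Matrix(matrix(c(1, 2, 3, 7, 7, 7), 2, byrow = TRUE),
                            sparse = TRUE,
                            dimnames = list(c("g1", "g2"), c("a", "b", "c"))),
    total_umi = rep(1, 3), mito_frac = rep(0, 3),
    gene_ids = c("g1", "g2"), cell_ids = c("a", "b", "c")),
    class = "norm_matrix")
  sc <- regress_and_scale(norm)
  expect_equal(unname(sc$matrix[1, ]), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(unname(sc$matrix[2, ]), c(0, 0, 0))   # constant gene
  # clipping
  set.seed(1)
  v <- c(rep(0, 400), 60)
  norm$matrix <- Matrix::Matrix(rbind(g1 = v, g2 = v), sparse = TRUE)
  norm$total_umi <- rep(1, 401)
  norm$mito_frac <- rep(0, 401)
  norm$cell_ids <- paste0("c", 1:401)
  sc <- regress_and_scale(norm, clip = 10)
  expect_equal(max(sc$matrix), 10)
})

test_that("a covariate equal to the gene zeroes it out; redundancy warns", {
  set.seed(2)
  e <- matrix(rnorm(5 * 20, 5), 5, 20,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:20)))
  norm <- structure(list(matrix = Matrix::Matrix(e, sparse = TRUE),
                         total_umi = rep(1, 20), mito_frac = rep(0, 20),
                         gene_ids = rownames(e), cell_ids = colnames(e)),
                    class = "norm_matrix")
  sc <- regress_and_scale(norm, covariates = cbind(x = e[1, ]))
  expect_equal(unname(sc$matrix[1, ]), rep(0, 20), tolerance = 1e-10)
  expect_warning(
    regress_and_scale(norm, covariates = cbind(x = e[1, ], y = 2 * e[1, ])),
    "rank-deficient")
})

test_that("variable-gene selection finds the overdispersed gene", {
  set.seed(3)
  n <- 200
  counts <- matrix(rpois(101 * n, 5), 101, n)
  # gene 101: same mean, ~10x the variance (half the cells doubled, half zeroed)
  hot <- rpois(n, 5) * sample(c(0, 2), n, replace = TRUE)
  counts[101, ] <- hot
  dimnames(counts) <- list(c(sprintf("bg%03d", 1:100), "hot"),
                           sprintf("c%03d", seq_len(n)))
  norm <- normalize_counts(raw_counts(counts))
  vg <- select_variable_genes(norm, min_dispersion_z = 1)
  expect_true("hot" %in% vg)
  expect_true(all(vg %in% norm$gene_ids))
  expect_false(anyDuplicated(vg) > 0)
  # constant genes are never selected
  counts2 <- rbind(counts, flat = rep(4, n))
  norm2 <- normalize_counts(raw_counts(counts2))
  expect_false("flat" %in% select_variable_genes(norm2))
})

test_that("PCA separates offset clouds and reports nonincreasing sdev", {
  blobs <- make_blobs(rbind(c(0, 0, 0), c(10, 0, 0)), 40, noise_sd = 1,
                      seed = 4)
  sc <- structure(list(matrix = t(scale(blobs$x, scale = FALSE)),
                       gene_ids = paste0("g", 1:3),
                       cell_ids = paste0("c", 1:80)),
                  class = "scaled_matrix")
  pc <- compute_pca(sc, 2)
  expect_true(all(diff(pc$sdev) <= 1e-12))
  expect_lt(abs(sum(pc$scores[, 1] * pc$scores[, 2])),
            1e-6 * sqrt(sum(pc$scores[, 1]^2) * sum(pc$scores[, 2]^2)))
  # silhouette of the two clouds on PC1
  p1 <- pc$scores[, 1]
  sil <- vapply(seq_along(p1), function(i) {
    own <- blobs$labels[i]
    a <- mean(abs(p1[i] - p1[blobs$labels == own][-match(i, which(blobs$labels == own))]))
    b <- mean(abs(p1[i] - p1[blobs$labels != own]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.8)
  expect_error(compute_pca(sc, 100), "exceeds")
  # identical cells: zero embedding with a warning
  sc0 <- structure(list(matrix = matrix(0, 3, 10),
                        gene_ids = paste0("g", 1:3),
                        cell_ids = paste0("c", 1:10)),
                   class = "scaled_matrix")
  expect_warning(pc0 <- compute_pca(sc0, 2), "identical")
  expect_equal(pc0$sdev, c(0, 0))
})

test_that("z-score + PCA agrees with a direct eigendecomposition", {
  set.seed(5)
  e <- matrix(rnorm(30 * 25), 30, 25,
              dimnames = list(paste0("g", 1:30), paste0("c", 1:25)))
  norm <- structure(list(matrix = Matrix::Matrix(abs(e), sparse = TRUE),
                         total_umi = rep(1, 25), mito_frac = rep(0, 25),
                         gene_ids = rownames(e), cell_ids = colnames(e)),
                    class = "norm_matrix")
  sc <- regress_and_scale(norm)
  pc <- compute_pca(sc, 5)
  # oracle: eigendecomposition of the covariance of the z-scored matrix
  z <- t(scale(t(as.matrix(norm$matrix))))  # genes x cells, sample sd
  x <- scale(t(z), scale = FALSE)
  ev <- eigen(crossprod(x) / (nrow(x) - 1))
  expect_equal(pc$sdev[1:5], sqrt(ev$values[1:5]), tolerance = 1e-8)
  for (j in 1:5) {
    direct <- as.numeric(x %*% ev$vectors[, j])
    expect_equal(abs(as.numeric(cor(pc$scores[, j], direct))), 1,
                 tolerance = 1e-6)
  }
})
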