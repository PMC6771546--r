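#' Read a UMI count matrix
#'
#' Reads 10x-style Matrix Market directories or dense delimited tables into a
#' genes-by-cells raw count object. Matrix Market directories must contain a
#' \code{matrix.mtx[.gz]} plus a gene table (\code{genes.tsv} /
#' \code{features.tsv}, 2- or 3-column dialects) and \code{barcodes.tsv};
#' dense tables have gene ids in the first column and cell ids in the header
#' unless \code{orientation = "cells_by_genes"}.
#'
#' Duplicated gene symbols are disambiguated by suffixing \code{-1}, \code{-2},
#' ... in order of appearance.
#'
#' @param path directory (for \code{mtx_dir}) or file path.
#' @param format one of \code{"mtx_dir"}, \code{"csv"}, \code{"tsv"}; guessed
#'   from the path when omitted.
#' @param orientation for dense tables, how the file is laid out on disk.
#' @param mito_pattern gene-symbol prefix flagging mitochondrial genes,
#'   matched case-insensitively.
#' @return an object of class \code{"raw_counts"}: a list with \code{matrix}
#'   (sparse \code{dgCMatrix}, genes x cells), \code{gene_ids},
#'   \code{cell_ids}, \code{mito_pattern}.
#' @export
read_counts <- function(path, format = c("auto", "mtx_dir", "csv", "tsv"),
                        orientation = c("genes_by_cells", "cells_by_genes"),
                        mito_pattern = "MT-") {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx_dir"
      else if (grepl("\\.csv(\\.gz)?$", path)) "csv" else "tsv"
  }
  if (format == "mtx_dir") {
    if (!dir.exists(path)) stop("directory not found: ", path)
    find1 <- function(names) {
      for (n in names) {
        p <- file.path(path, n)
        if (file.exists(p)) return(p)
      }
      stop("none of [", paste(names, collapse = ", "), "] found in ", path)
    }
    mtx <- find1(c("matrix.mtx", "matrix.mtx.gz"))
    gtab <- find1(c("genes.tsv", "genes.tsv.gz", "features.tsv", "features.tsv.gz"))
    btab <- find1(c("barcodes.tsv", "barcodes.tsv.gz"))
    m <- Matrix::readMM(mtx)
    genes <- utils::read.table(gtab, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE, quote = "")
    # v2 tables are <id, symbol>, v3 <id, symbol, type>; 1-column also accepted
    gene_ids <- if (ncol(genes) >= 2) as.character(genes[[2]]) else as.character(genes[[1]])
    cell_ids <- as.character(utils::read.table(btab, sep = "\t", header = FALSE,
                                               stringsAsFactors = FALSE)[[1]])
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (format == "csv") "," else "\t"
    tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                             check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(tab)
    if (orientation == "cells_by_genes") m <- t(m)
    gene_ids <- rownames(m)
    cell_ids <- colnames(m)
  }
  raw_counts(m, gene_ids, cell_ids, mito_pattern)
}

#' Construct a raw count object from a matrix
#'
#' @param matrix numeric matrix or sparse Matrix, genes x cells, non-negative
#'   integers.
#' @param gene_ids,cell_ids row / column identifiers; default to dimnames.
#' @inheritParams read_counts
#' @return a \code{"raw_counts"} object.
#' @export
raw_counts <- function(matrix, gene_ids = rownames(matrix),
                       cell_ids = colnames(matrix), mito_pattern = "MT-") {
  if (is.null(gene_ids)) stop("gene ids are required")
  if (is.null(cell_ids)) stop("cell ids are required")
  if (length(gene_ids) != nrow(matrix))
    stop("gene table has ", length(gene_ids), " rows but matrix has ",
         nrow(matrix), " genes")
  if (length(cell_ids) != ncol(matrix))
    stop("barcode table has ", length(cell_ids), " rows but matrix has ",
         ncol(matrix), " cells")
  m <- methods::as(methods::as(Matrix::Matrix(matrix, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  v <- m@x
  if (any(v < 0)) stop("counts must be non-negative")
  if (any(v != round(v))) stop("counts must be integral")
  gene_ids <- .dedup_ids(as.character(gene_ids))
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(cell_ids)) stop("cell ids are not unique")
  dimnames(m) <- list(gene_ids, cell_ids)
  structure(list(matrix = m, gene_ids = gene_ids, cell_ids = cell_ids,
                 mito_pattern = mito_pattern),
            class = "raw_counts")
}

# suffix every occurrence of a duplicated id with -1, -2, ... in order
.dedup_ids <- function(ids) {
  dup <- ids %in% ids[duplicated(ids)]
  if (!any(dup)) return(ids)
  for (nm in unique(ids[dup])) {
    at <- which(ids == nm)
    ids[at] <- paste0(nm, "-", seq_along(at))
  }
  ids
}

#' @export
print.raw_counts <- function(x, ...) {
  cat(sprintf("raw UMI counts: %d genes x %d cells (%.2f%% non-zero)\n",
              nrow(x$matrix), ncol(x$matrix),
              100 * Matrix::nnzero(x$matrix) / prod(dim(x$matrix))))
  invisible(x)
}

#' @export
dim.raw_counts <- function(x) dim(x$matrix)

#' Write run results to a directory
#'
#' Emits, for an \code{\link{ikap}} result: one cell-to-group assignment TSV
#' and one DE-gene TSV per candidate, the gap and gap-increase matrices, a
#' performance-summary TSV, and a JSON manifest recording the configuration,
#' seed and candidate list. For an ontology (\code{\link{build_ontology}}),
#' writes the nested JSON plus per-node artifacts under a directory tree.
#'
#' @param result an \code{"ikap"} or \code{"ikap_ontology"} object.
#' @param outdir output directory, created if missing.
#' @return invisibly, the paths written.
#' @export
write_results <- function(result, outdir) {
  UseMethod("write_results")
}

#' @export
write_results.ikap <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wtsv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  gm <- result$gap
  gap_df <- data.frame(nPC = as.integer(rownames(gm$gap)), gm$gap,
                       check.names = FALSE)
  inc_df <- data.frame(nPC = as.integer(rownames(gm$increase)), gm$increase,
                       check.names = FALSE)
  paths <- c(paths, wtsv(gap_df, "gap_matrix.tsv"),
             wtsv(inc_df, "gap_increase_matrix.tsv"))
  if (length(result$candidates) == 0) {
    warning("no candidate sets; writing manifest and gap matrices only")
  }
  for (cand in result$candidates) {
    assign_df <- data.frame(cell_id = result$cell_ids,
                            group = cand$grouping$labels)
    paths <- c(paths,
               wtsv(assign_df, sprintf("assignment_%s.tsv", cand$name)),
               wtsv(cand$de, sprintf("de_genes_%s.tsv", cand$name)))
  }
  if (!is.null(result$summary))
    paths <- c(paths, wtsv(result$summary$table, "performance_summary.tsv"))
  manifest <- list(
    config = unclass(result$config),
    bounds = result$bounds,
    candidates = lapply(result$candidates, function(cand)
      list(name = cand$name, nPC = cand$nPC, k = cand$k,
           gap_increase = cand$gap_increase)),
    threshold = result$selection_threshold,
    best = if (length(result$candidates)) result$candidates[[result$best]]$name else NULL,
    n_cells = length(result$cell_ids),
    r_version = R.version.string
  )
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(paths, mp))
}

#' @export
write_results.ikap_ontology <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_node <- function(node, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(node$result)) write_results(node$result, dir)
    for (i in seq_along(node$children))
      write_node(node$children[[i]], file.path(dir, names(node$children)[i]))
  }
  write_node(result$root, file.path(outdir, "root"))
  jp <- file.path(outdir, "ontology.json")
  jsonlite::write_json(as_ontology_list(result), jp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(jp)
}

#' Read back a cell-to-group assignment TSV
#'
#' @param path a TSV written by \code{\link{write_results}} with columns
#'   \code{cell_id} and \code{group}.
#' @return a data.frame with character \code{cell_id} and integer \code{group}.
#' @export
read_assignment <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer"))
  df
}
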