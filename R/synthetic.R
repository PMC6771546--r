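#' Specification of a hierarchical synthetic UMI dataset
#'
#' Describes a mixture of a few well-separated major cell populations, each
#' optionally split into subpopulations carried by fewer / weaker marker
#' genes. Counts are negative-binomial with per-gene log-normal baseline
#' means, multiplicative marker effects, and log-normal library-size factors;
#' a small block of genes is prefixed \code{MT-} and scaled to a target
#' mitochondrial fraction so quality-control filters have something to see.
#'
#' @param n_genes total number of genes (including mitochondrial ones).
#' @param majors list of major populations, each a list with \code{n_cells},
#'   \code{n_markers}, \code{marker_log_effect} (> 0, natural-log units).
#' @param subs optional list parallel to \code{majors}; each element either
#'   NULL or a list with \code{fractions} (summing to 1), \code{n_markers},
#'   \code{marker_log_effect} describing subpopulations of that major.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline negative-binomial mean.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param library_sdlog log-normal sd of the per-cell library-size factor
#'   (mean factor fixed at 1).
#' @param mito_fraction_mean target expected mitochondrial UMI fraction.
#' @param n_mito_genes number of \code{MT-} genes.
#' @param seed integer seed.
#' @return an object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n_genes, majors, subs = NULL,
                           baseline_meanlog = log(0.2), baseline_sdlog = 1,
                           dispersion = 2, library_sdlog = 0.25,
                           mito_fraction_mean = 0.02, n_mito_genes = 10L,
                           seed = 1L) {
  if (is.null(subs)) subs <- vector("list", length(majors))
  stopifnot(length(subs) == length(majors), n_genes > n_mito_genes)
  for (m in majors)
    stopifnot(m$n_cells >= 1, m$n_markers >= 0,
              is.null(m$marker_log_effect) || m$marker_log_effect > 0 ||
                m$n_markers == 0)
  for (s in subs) if (!is.null(s)) {
    stopifnot(abs(sum(s$fractions) - 1) < 1e-8, s$marker_log_effect > 0)
  }
  n_markers_total <- sum(vapply(majors, `[[`, numeric(1), "n_markers")) +
    sum(vapply(subs, function(s)
      if (is.null(s)) 0 else length(s$fractions) * s$n_markers, numeric(1)))
  if (n_markers_total > n_genes - n_mito_genes)
    stop("marker sets exceed the number of non-mitochondrial genes")
  structure(list(n_genes = as.integer(n_genes), majors = majors, subs = subs,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion, library_sdlog = library_sdlog,
                 mito_fraction_mean = mito_fraction_mean,
                 n_mito_genes = as.integer(n_mito_genes),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic UMI dataset with ground truth
#'
#' Per cell, counts are drawn as NB(mean = baseline * exp(marker effects of
#' its major group and subgroup) * library factor, size = dispersion).
#' Marker gene sets are disjoint across all groups and subgroups.
#' Deterministic for a fixed spec (the spec carries the seed).
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with \code{counts} (a \code{"raw_counts"}) and \code{truth}
#'   (list with \code{major_label}, \code{sub_label} per cell and
#'   \code{markers}, a named list group -> gene ids).
#' @export
simulate_cells <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_mito <- spec$n_mito_genes
  g_total <- spec$n_genes
  gene_ids <- c(paste0("MT-", seq_len(n_mito)),
                sprintf("Gene%04d", seq_len(g_total - n_mito)))
  base <- stats::rlnorm(g_total, spec$baseline_meanlog, spec$baseline_sdlog)
  # scale the mitochondrial block to the target expected fraction
  if (n_mito > 0 && spec$mito_fraction_mean > 0) {
    tgt <- spec$mito_fraction_mean / (1 - spec$mito_fraction_mean) *
      sum(base[-seq_len(n_mito)])
    base[seq_len(n_mito)] <- base[seq_len(n_mito)] *
      tgt / sum(base[seq_len(n_mito)])
  }
  n_major <- length(spec$majors)
  major_sizes <- vapply(spec$majors, `[[`, numeric(1), "n_cells")
  major_label <- rep(seq_len(n_major), major_sizes)
  n_cells <- sum(major_sizes)
  sub_label <- rep(NA_integer_, n_cells)
  # assign disjoint marker blocks from the non-mitochondrial genes
  next_gene <- n_mito + 1L
  take_markers <- function(n) {
    if (n == 0) return(integer(0))
    at <- next_gene:(next_gene + n - 1L)
    next_gene <<- next_gene + n
    at
  }
  log_mu <- matrix(log(base), g_total, n_cells)
  markers <- list()
  for (m in seq_len(n_major)) {
    cells <- which(major_label == m)
    mk <- take_markers(spec$majors[[m]]$n_markers)
    if (length(mk)) {
      log_mu[mk, cells] <- log_mu[mk, cells] + spec$majors[[m]]$marker_log_effect
      markers[[paste0("major", m)]] <- gene_ids[mk]
    }
    s <- spec$subs[[m]]
    if (!is.null(s)) {
      n_sub <- length(s$fractions)
      sizes <- diff(round(cumsum(c(0, s$fractions)) * length(cells)))
      sl <- rep(seq_len(n_sub), sizes)
      sub_label[cells] <- sl
      for (j in seq_len(n_sub)) {
        mk_s <- take_markers(s$n_markers)
        if (length(mk_s)) {
          log_mu[mk_s, cells[sl == j]] <-
            log_mu[mk_s, cells[sl == j]] + s$marker_log_effect
          markers[[paste0("major", m, ".sub", j)]] <- gene_ids[mk_s]
        }
      }
    }
  }
  # library factors with mean 1
  lib <- stats::rlnorm(n_cells, -spec$library_sdlog^2 / 2, spec$library_sdlog)
  mu <- exp(log_mu) * lib[col(log_mu)]
  counts <- matrix(stats::rnbinom(length(mu), size = spec$dispersion,
                                  mu = mu), g_total, n_cells)
  dimnames(counts) <- list(gene_ids, sprintf("cell%05d", seq_len(n_cells)))
  list(counts = raw_counts(counts),
       truth = list(major_label = major_label, sub_label = sub_label,
                    markers = markers,
                    expected_library_size = sum(base)))
}

#' Documented synthetic presets
#'
#' \describe{
#'   \item{flat5}{5 well-separated major populations of 150 cells each, 40
#'     markers per group at 2.5 natural-log units; 1500 genes. The canonical
#'     parameter-recovery fixture.}
#'   \item{hier3x3}{3 major populations (360, 160, 160 cells); the largest is
#'     split into 3 equal subpopulations carried by 40 markers at half the
#'     major effect (1.25 vs 2.5 natural-log units).}
#'   \item{single_blob}{one structureless population (300 cells, no markers).}
#'   \item{pbmc_like}{7 major populations with strong size imbalance
#'     (360..48 cells), 30 markers each at 2.0 — the group-count regime of a
#'     PBMC-style experiment.}
#' }
#'
#' @param name preset name.
#' @param seed seed stored in the returned spec.
#' @return a \code{\link{synthetic_spec}}.
#' @export
preset <- function(name = c("flat5", "hier3x3", "single_blob", "pbmc_like"),
                   seed = 1L) {
  name <- match.arg(name)
  major <- function(n, m, eff) list(n_cells = n, n_markers = m,
                                    marker_log_effect = eff)
  switch(name,
    flat5 = synthetic_spec(
      n_genes = 1500L,
      majors = rep(list(major(150L, 40L, 2.5)), 5),
      seed = seed),
    hier3x3 = synthetic_spec(
      n_genes = 1500L,
      majors = list(major(360L, 40L, 2.5), major(160L, 40L, 2.5),
                    major(160L, 40L, 2.5)),
      subs = list(list(fractions = rep(1 / 3, 3), n_markers = 40L,
                       marker_log_effect = 1.25), NULL, NULL),
      seed = seed),
    single_blob = synthetic_spec(
      n_genes = 1200L,
      majors = list(major(300L, 0L, 0)),
      seed = seed),
    pbmc_like = synthetic_spec(
      n_genes = 1600L,
      majors = mapply(major, c(360L, 300L, 180L, 144L, 96L, 72L, 48L),
                      30L, 2.0, SIMPLIFY = FALSE),
      seed = seed)
  )
}
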