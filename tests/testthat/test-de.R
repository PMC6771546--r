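test_that("AUROC matches its closed-form examples", {
  expect_equal(compute_auroc(c(5, 6), c(1, 2)), 1.0)
  expect_equal(compute_auroc(c(3, 3, 3), c(3, 3)), 0.5)
  expect_equal(compute_auroc(c(3, 1), c(2, 0)), 0.75)
  expect_error(compute_auroc(numeric(0), 1), "nonempty")
})

test_that("AUROC equals brute-force pair enumeration, ties half-weighted", {
  brute <- function(a, b) {
    s <- 0
    for (x in a) for (y in b)
      s <- s + (x > y) + 0.5 * (x == y)
    s / (length(a) * length(b))
  }
  set.seed(40)
  for (rep in 1:60) {
    n_in <- sample(1:120, 1)
    n_out <- sample(1:80, 1)
    # integer values force plenty of ties
    a <- sample(0:5, n_in, replace = TRUE)
    b <- sample(0:5, n_out, replace = TRUE)
    expect_equal(compute_auroc(a, b), brute(a, b), tolerance = 1e-12)
  }
})

test_that("one-vs-rest DE reports planted upregulated markers only", {
  mk <- make_marker_counts(n_groups = 3, cells_per = 50, n_noise = 30)
  norm <- normalize_counts(mk$counts)
  de <- find_de_genes(norm, make_grouping(mk$labels))
  # each group's clean marker is reported with AUROC 1
  for (g in 0:2) {
    row <- de[de$gene == paste0("Marker", g + 1) & de$group == g, ]
    expect_equal(nrow(row), 1)
    expect_equal(row$auroc, 1.0)
    expect_gt(row$avg_logFC, 0)
    expect_lte(row$p_adj, 0.05)
  }
  # a marker of group 1 is strictly lower in the other groups: never reported
  # as upregulated there
  expect_false(any(de$gene == "Marker1" & de$group != 0))
  expect_true(all(de$avg_logFC > 0))
  expect_true(all(de$pct_in >= 0 & de$pct_in <= 1))
})

test_that("genes with identical distributions are not reported", {
  set.seed(41)
  m <- matrix(rpois(40 * 180, 2), 40, 180,
              dimnames = list(sprintf("G%02d", 1:40), sprintf("c%03d", 1:180)))
  norm <- normalize_counts(raw_counts(m))
  labels <- rep(0:2, each = 60)
  de <- find_de_genes(norm, make_grouping(labels))
  expect_equal(nrow(de), 0)
})

test_that("groups with fewer than 3 cells are skipped with a warning", {
  mk <- make_marker_counts(n_groups = 2, cells_per = 30)
  labels <- mk$labels
  labels[1:2] <- 2L   # a 2-cell group
  norm <- normalize_counts(mk$counts)
  expect_warning(de <- find_de_genes(norm, make_grouping(labels)),
                 "fewer than 3")
  expect_false(2 %in% de$group)
})

test_that("classification-error aggregation follows the product-sum-mean rule", {
  # one group with fraction 0.3 and relative error 0.2 at every nsplit,
  # the others perfect -> final error = 0.06 exactly
  rel <- rbind(rep(0.2, 11), matrix(0, 2, 11))
  agg <- aggregate_classification_error(rel, c(0.3, 0.4, 0.3))
  expect_equal(agg$final_error, 0.06)
  expect_equal(unname(agg$set_error_by_nsplit), rep(0.06, 11))
  # varying over nsplit averages set-level errors
  rel2 <- rbind(seq(0.2, 0.1, length.out = 11), matrix(0, 2, 11))
  agg2 <- aggregate_classification_error(rel2, c(0.5, 0.25, 0.25))
  expect_equal(agg2$final_error, mean(seq(0.2, 0.1, length.out = 11)) * 0.5)
  expect_error(aggregate_classification_error(rel * 10, c(0.3, 0.4, 0.3)))
})

test_that("perfectly separable groups get zero final error; errors shrink
          with stronger markers", {
  mk <- make_marker_counts(n_groups = 3, cells_per = 40, marker_value = 8)
  norm <- normalize_counts(mk$counts)
  grouping <- make_grouping(mk$labels)
  de <- find_de_genes(norm, grouping)
  rep1 <- classification_error(norm, grouping, de)
  expect_equal(rep1$final_error, 0)
  expect_true(all(rep1$per_group >= 0 & rep1$per_group <= 1))
  # relative errors are nonincreasing in nsplit for every tree
  expect_true(all(apply(rep1$per_group, 1, function(r) all(diff(r) <= 1e-12))))
  expect_error(classification_error(norm, grouping, de[0, ]), "no DE genes")

  # marker-strength sweep: weaker markers cannot reduce the error below
  # stronger ones
  noisy_counts <- function(strength, seed) {
    set.seed(seed)
    n <- 120
    labels <- rep(0:2, each = 40)
    m <- matrix(rpois(30 * n, 2), 30, n)
    for (g in 0:2) {
      mu <- ifelse(labels == g, 2 * strength, 2)
      m <- rbind(m, rpois(n, mu))
    }
    dimnames(m) <- list(c(sprintf("N%02d", 1:30), sprintf("M%d", 1:3)),
                        sprintf("c%03d", 1:n))
    list(norm = normalize_counts(raw_counts(m)),
         grouping = make_grouping(labels))
  }
  errs <- vapply(c(2, 8), function(s) {
    d <- noisy_counts(s, seed = 42)
    de_s <- find_de_genes(d$norm, d$grouping, min_logfc = 0.1)
    classification_error(d$norm, d$grouping, de_s)$final_error
  }, numeric(1))
  expect_lte(errs[2], errs[1])
  expect_true(all(errs >= 0 & errs <= 1))
})

test_that("summary medians, top-10 rule and best marking are correct", {
  de <- data.frame(
    gene = sprintf("g%02d", 1:24),
    group = rep(0:2, c(4, 8, 12)),
    avg_logFC = rep(c(2, 1.5, 1), c(4, 8, 12)),
    p = 1e-10, p_adj = 1e-8, pct_in = 1, pct_out = 0,
    auroc = rep(c(0.95, 0.86, 0.82), c(4, 8, 12)))
  grouping <- make_grouping(rep(0:2, c(10, 10, 10)))
  mk_cand <- function(name, k, err) {
    list(name = name, nPC = 5, k = k, gap_increase = 0.5, grouping = grouping,
         de = de, classifier = list(final_error = err))
  }
  s <- summarize_candidates(list(mk_cand("A", 3, 0.04), mk_cand("B", 4, 0.02)))
  tab <- s$table
  # counts above cutoffs: per group (4, 8, 12) genes, all > 0.8 -> median 8;
  # > 0.85: (4, 8, 0) -> median 4; > 0.9: (4, 0, 0) -> median 0
  expect_equal(tab$n_de_auroc_gt_0.8[1], 8)
  expect_equal(tab$n_de_auroc_gt_0.85[1], 4)
  expect_equal(tab$n_de_auroc_gt_0.9[1], 0)
  # top-10 rule: group 0 has 4 qualifying genes -> mean over all 4 = 2;
  # group 2 has 12 -> mean of top 10 = 1; median of (2, 1.5, 1) = 1.5
  expect_equal(tab$median_top10_avg_logFC[1], 1.5)
  expect_equal(tab$median_top10_avg_log2FC[1], 1.5 / log(2))
  # lower error wins the best flag
  expect_equal(s$best, 2)
  expect_equal(tab$is_best, c(FALSE, TRUE))
  expect_equal(sum(tab$is_best), 1)
  # tie on error -> smaller k
  s2 <- summarize_candidates(list(mk_cand("A", 4, 0.02), mk_cand("B", 3, 0.02)))
  expect_equal(s2$table$name[s2$best], "B")
})

test_that("summary metrics are invariant under group relabeling", {
  mk <- make_marker_counts(n_groups = 3, cells_per = 40)
  norm <- normalize_counts(mk$counts)
  build <- function(labels) {
    g <- make_grouping(labels)
    de <- find_de_genes(norm, g)
    cls <- classification_error(norm, g, de)
    summarize_candidates(list(list(name = "X", nPC = 2, k = 3,
                                   gap_increase = 1, grouping = g, de = de,
                                   classifier = cls)))$table
  }
  t1 <- build(mk$labels)
  t2 <- build((mk$labels + 1L) %% 3L)
  cols <- c("median_top10_avg_logFC", "classification_error",
            "n_de_auroc_gt_0.8", "n_de_auroc_gt_0.85", "n_de_auroc_gt_0.9")
  expect_equal(t1[cols], t2[cols])
})
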