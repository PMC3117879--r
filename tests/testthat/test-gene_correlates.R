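toy_spw_genes <- function(gene_sets, ids) {
  data.frame(subpathway_id = ids, pathway_id = "p", class_label = "c",
             n_enzymes = 1L, n_genes = lengths(gene_sets),
             enzymes = I(replicate(length(gene_sets), "e", simplify = FALSE)),
             genes = I(gene_sets), stringsAsFactors = FALSE)
}

test_that("gene class labels enforce HK/TS disjointness", {
  expect_error(gene_class_labels(housekeeping_genes = c("a", "b"),
                                 tissue_specific_genes = c("b", "c")),
               "disjoint")
  lab <- gene_class_labels(c("a", "a", "b"), "c", "d", "e")
  expect_equal(lab$disease_genes, c("a", "b"))
})

test_that("ratio profiles equal direct set-intersection counts", {
  net <- toy_network(c("d1", "d2", "d1"), c("s1", "s1", "s2"))
  spw <- toy_spw_genes(list(c("g1", "g2", "g3", "g4"), c("g5", "g6")),
                       c("s1", "s2"))
  lab <- gene_class_labels(disease_genes = c("g1", "g2"),
                           essential_genes = "g5",
                           housekeeping_genes = "g3",
                           tissue_specific_genes = "g6")
  prof <- gene_ratio_profiles(net, spw, lab)
  p1 <- prof[prof$subpathway_id == "s1", ]
  expect_equal(p1$degree, 2)
  expect_equal(p1$ratio_disease, 0.5)
  expect_equal(p1$ratio_hk, 0.25)
  expect_equal(p1$ratio_essential, 0)
  p2 <- prof[prof$subpathway_id == "s2", ]
  expect_equal(p2$ratio_essential, 0.5)
  expect_equal(p2$ratio_ts, 0.5)

  # empty labels -> all-zero ratios; covering labels -> ratio 1
  none <- gene_ratio_profiles(net, spw, gene_class_labels())
  expect_true(all(none$ratio_disease == 0))
  all_lab <- gene_class_labels(disease_genes = paste0("g", 1:6))
  expect_true(all(gene_ratio_profiles(net, spw, all_lab)$ratio_disease == 1))

  # empty gene sets are excluded with a message
  spw0 <- toy_spw_genes(list(c("g1"), character(0)), c("s1", "s2"))
  expect_message(p0 <- gene_ratio_profiles(net, spw0, lab), "excluded")
  expect_equal(p0$subpathway_id, "s1")
})

test_that("trend tests recover an exact linear relation and reject degenerate input", {
  prof <- data.frame(subpathway_id = paste0("s", 1:10), degree = 1:10,
                     ratio_disease = 0.05 * (1:10) + 0.1)
  tr <- suppressWarnings(trend_test(prof, "ratio_disease"))
  expect_equal(tr$slope, 0.05, tolerance = 1e-10)
  expect_lt(tr$p_value, 1e-10)
  expect_equal(tr$n, 10)

  prof$ratio_disease <- 0.9 - 0.04 * (1:10)
  expect_lt(suppressWarnings(trend_test(prof, "ratio_disease"))$slope, 0)

  expect_error(trend_test(prof[1:2, ], "ratio_disease"), ">= 3")
  prof$degree <- 5
  expect_error(trend_test(prof, "ratio_disease"), "zero degree variance")
})

test_that("shuffled responses keep the trend-test size near nominal", {
  set.seed(61)
  prof <- data.frame(degree = rpois(60, 8) + 1, ratio = runif(60))
  hits <- mean(replicate(200, {
    prof$ratio <- sample(prof$ratio)
    trend_test(prof, "ratio")$p_value < 0.05
  }))
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lte(hits, 0.05 + 3 * se)
})

test_that("binned summaries match hand-computed quantile bins", {
  b1 <- binned_summary(1:7, c(2, 4, 6, 8, 10, 12, 14), n_bins = 1)
  expect_equal(b1$mean_y, 8)
  expect_equal(b1$sd_y, sd(c(2, 4, 6, 8, 10, 12, 14)))

  bc <- binned_summary(1:10, rep(3, 10), n_bins = 5)
  expect_true(all(bc$mean_y == 3))
  expect_true(all(bc$sd_y == 0))

  x <- 1:20; y <- c(1:10, rep(0, 10))
  b4 <- binned_summary(x, y, n_bins = 4)
  expect_equal(b4$n, rep(5L, 4))
  expect_equal(b4$mean_y, c(mean(1:5), mean(6:10), 0, 0))
  expect_equal(b4$bin_center, c(3, 8, 13, 18))

  expect_error(binned_summary(1:3, 1:3, n_bins = 5), "exceeds")
})

test_that("pairwise coexpression averages the right pair set", {
  tiss <- 6
  base <- matrix(rnorm(5 * tiss), 5, tiss,
                 dimnames = list(paste0("g", 1:5), NULL))
  base["g2", ] <- base["g1", ]                     # identical pair
  # zero-mean profiles with zero dot product -> Pearson exactly 0
  ortho <- rbind(o1 = c(1, 1, -1, -1), o2 = c(1, -1, 1, -1))

  expect_equal(pairwise_coexpression(base, c("g1", "g2"), c("g1", "g2")), 1)
  expect_equal(pairwise_coexpression(ortho, "o1", "o2"), 0, tolerance = 1e-12)

  # brute-force pair loop oracle on the 5-gene fixture
  A <- c("g1", "g2", "g3"); B <- c("g3", "g4", "g5")
  cm <- stats::cor(t(base))
  pairs <- list()
  for (a in A) for (b in B) {
    if (a == b) next
    key <- paste(sort(c(a, b)), collapse = "|")
    pairs[[key]] <- cm[a, b]
  }
  expect_equal(pairwise_coexpression(base, A, B),
               mean(unlist(pairs)))

  # no admissible pair -> NA sentinel, not zero
  expect_true(is.na(pairwise_coexpression(base, "g1", "g1")))
  expect_true(is.na(pairwise_coexpression(base, "absent", "g1")))
  flat <- rbind(base, flatgene = rep(1, tiss))
  expect_true(is.na(pairwise_coexpression(flat, "flatgene", "flatgene")))
})

test_that("coexpression summary composes the pairwise oracle per subpathway", {
  set.seed(71)
  genes <- paste0("g", 1:12)
  expr <- matrix(rnorm(12 * 8), 12, 8, dimnames = list(genes, NULL))
  net <- toy_network(c("d1", "d2"), c("s1", "s2"))
  spw <- toy_spw_genes(list(genes[1:6], genes[5:12]), c("s1", "s2"))
  lab <- gene_class_labels(disease_genes = genes[c(1, 2, 7)],
                           essential_genes = genes[3],
                           housekeeping_genes = genes[8],
                           tissue_specific_genes = genes[c(4, 9)])
  cs <- coexpression_summary(net, spw, lab, expr)
  row1 <- cs$per_subpathway[cs$per_subpathway$subpathway_id == "s1", ]
  expect_equal(row1$disease_disease,
               pairwise_coexpression(expr, genes[1:2], genes[1:2]))
  expect_equal(row1$disease_essential,
               pairwise_coexpression(expr, genes[1:2], genes[3]))
  expect_equal(row1$all_all,
               pairwise_coexpression(expr, genes[1:6], genes[1:6]))
  # "other" genes of s1 are g5, g6 (in no label set)
  expect_equal(row1$disease_other,
               pairwise_coexpression(expr, genes[1:2], genes[5:6]))
  expect_equal(unname(cs$medians["all_all"]),
               median(cs$per_subpathway$all_all))

  # invariant to gene and tissue orderings
  perm <- expr[sample(rownames(expr)), sample(ncol(expr))]
  cs2 <- coexpression_summary(net, spw, lab, perm)
  expect_equal(cs2$per_subpathway, cs$per_subpathway)
})

test_that("identical expression profiles give medians 1 and Wilcoxon P = 1", {
  genes <- paste0("g", 1:7)  # g7 carries no label ("other" group)
  prof <- rnorm(5)
  expr <- matrix(rep(prof, each = 7), 7, 5, dimnames = list(genes, NULL))
  net <- toy_network("d1", "s1")
  spw <- toy_spw_genes(list(genes), "s1")
  lab <- gene_class_labels(disease_genes = genes[1:3],
                           essential_genes = genes[4],
                           housekeeping_genes = genes[5],
                           tissue_specific_genes = genes[6])
  cs <- coexpression_summary(net, spw, lab, expr)
  expect_true(all(cs$medians == 1))
  expect_true(all(cs$wilcoxon_p == 1))
})
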