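test_that("one-mode projection links nodes sharing a neighbor", {
  # star: one subpathway serving three diseases -> disease triangle
  star <- toy_network(c("d1", "d2", "d3"), rep("s1", 3))
  pr <- one_mode_projection(star, "disease")
  expect_setequal(edge_key(pr$graph), c("d1 d2", "d1 d3", "d2 d3"))

  # two disjoint stars -> two disjoint cliques
  two <- toy_network(c("d1", "d2", "d3", "d4"), c("s1", "s1", "s2", "s2"))
  pr2 <- one_mode_projection(two, "disease")
  expect_setequal(edge_key(pr2$graph), c("d1 d2", "d3 d4"))

  expect_error(one_mode_projection(build_network(
    data.frame(disease_id = character(0), subpathway_id = character(0),
               p_value = numeric(0))), "disease"), "empty")
})

test_that("projection adjacency equals the shared-neighbor-count oracle", {
  set.seed(31)
  e <- unique(data.frame(d = paste0("d", sample(1:9, 40, TRUE)),
                         s = paste0("s", sample(1:7, 40, TRUE)),
                         stringsAsFactors = FALSE))
  net <- toy_network(e$d, e$s)
  for (t in 1:2) {
    pr <- one_mode_projection(net, "subpathway", min_shared = t)
    got <- edge_key(pr$graph)
    want <- character(0)
    ids <- names(net$subpathway_class)
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i >= j) next
      shared <- length(intersect(e$d[e$s == ids[i]], e$d[e$s == ids[j]]))
      if (shared >= t) want <- c(want, paste(ids[i], ids[j]))
    }
    expect_setequal(got, want)
  }
})

planted_projection <- function() {
  # 20 nodes in two classes; class A planted denser within itself
  nodes <- sprintf("n%02d", 1:20)
  classes <- stats::setNames(rep(c("A", "B"), each = 10), nodes)
  edges <- c("n01","n02", "n01","n03", "n02","n03", "n04","n05",
             "n06","n07", "n08","n09",          # within A
             "n11","n12", "n13","n14",          # within B
             "n01","n11", "n05","n15")          # across
  structure(list(graph = named_graph(nodes, edges), node_class = classes,
                 side = "disease"), class = "projection_graph")
}

test_that("analytic BD/BH match hand-computed counts on a planted fixture", {
  pr <- planted_projection()
  st <- bd_bh(pr, "A", mode = "analytic")
  # hand counts: 6 edges inside A, 2 leaving A; 10 edges total, N = 20
  expect_equal(st$m11, 6)
  expect_equal(st$m10, 2)
  p_bar <- 2 * 10 / (20 * 19)
  expect_equal(st$e11, p_bar * 10 * 9 / 2)
  expect_equal(st$e10, p_bar * 10 * 10)
  expect_equal(st$BD, 6 / (p_bar * 45))
  expect_equal(st$BH, 2 / (p_bar * 100))
  expect_gt(st$BD, 1)
  expect_lt(st$BH, 1)
})

test_that("permutation expectations agree with analytic ones within Monte-Carlo error", {
  pr <- planted_projection()
  an <- bd_bh(pr, "A", mode = "analytic")
  pe <- bd_bh(pr, "A", mode = "permutation", n_perm = 3000, seed = 9)
  # independent relabeling oracle to estimate the Monte-Carlo SEs
  el <- igraph::as_edgelist(pr$graph, names = TRUE)
  set.seed(123)
  sam <- replicate(500, {
    m <- sample(names(pr$node_class), 10)
    i1 <- el[, 1] %in% m; i2 <- el[, 2] %in% m
    c(sum(i1 & i2), sum(xor(i1, i2)))
  })
  expect_lt(abs(pe$e11 - an$e11), 3 * stats::sd(sam[1, ]) / sqrt(3000) + 0.02)
  expect_lt(abs(pe$e10 - an$e10), 3 * stats::sd(sam[2, ]) / sqrt(3000) + 0.02)
})

test_that("complete projections score exactly BD = BH = 1 analytically", {
  nodes <- letters[1:6]
  pr <- structure(list(
    graph = named_graph(nodes, as.vector(utils::combn(nodes, 2))),
    node_class = stats::setNames(rep(c("A", "B"), 3), nodes),
    side = "disease"), class = "projection_graph")
  st <- bd_bh(pr, "A", mode = "analytic")
  expect_equal(st$BD, 1)
  expect_equal(st$BH, 1)
})

test_that("degenerate classes raise an undefined-statistic error naming the class", {
  pr <- planted_projection()
  pr$node_class[] <- "A"  # complement empty -> e10 = 0
  expect_error(bd_bh(pr, "A"), "undefined for class 'A'")
  pr2 <- planted_projection()
  pr2$node_class[] <- "B"; pr2$node_class["n01"] <- "A"  # n1 = 1 -> e11 = 0
  expect_error(bd_bh(pr2, "A"), "undefined")
})

test_that("class tables cover present classes and average over defined ones", {
  dcl <- stats::setNames(rep(c("A", "B"), each = 5), paste0("d", 1:10))
  scl <- stats::setNames(rep("m", 4), paste0("s", 1:4))
  # class-assortative wiring: A diseases share s1/s2, B share s3/s4
  e <- data.frame(
    d = c(paste0("d", 1:5), paste0("d", 1:5), paste0("d", 6:10), paste0("d", 6:10), "d1"),
    s = c(rep("s1", 5), rep("s2", 5), rep("s3", 5), rep("s4", 5), "s3"),
    stringsAsFactors = FALSE)
  net <- toy_network(e$d, e$s, disease_class = dcl, subpathway_class = scl)
  ct <- class_table(net, "disease")
  expect_equal(nrow(ct$per_class), 2)
  expect_true(all(ct$per_class$BD > 1))
  expect_gt(ct$mean_BD, ct$mean_BH)
  expect_equal(ct$mean_BD, mean(ct$per_class$BD))

  # the edge-count identity: sum m11 + sum(m10)/2 = M for a partition
  pr <- one_mode_projection(net, "disease")
  M <- igraph::ecount(pr$graph)
  expect_equal(sum(ct$per_class$m11) + sum(ct$per_class$m10) / 2, M)
})

test_that("random class labels give mean BD near 1 on average", {
  set.seed(41)
  e <- unique(data.frame(d = paste0("d", sample(1:20, 120, TRUE)),
                         s = paste0("s", sample(1:12, 120, TRUE)),
                         stringsAsFactors = FALSE))
  net <- toy_network(e$d, e$s)
  pr <- one_mode_projection(net, "disease")
  n_d <- length(net$disease_class)
  bds <- replicate(200, {
    labs <- stats::setNames(sample(rep(c("A", "B", "C", "D"),
                                       length.out = n_d)),
                            names(net$disease_class))
    pr$node_class <- labs
    mean(vapply(c("A", "B", "C", "D"), function(cl) {
      tryCatch(bd_bh(pr, cl)$BD, error = function(e) NA_real_)
    }, numeric(1)), na.rm = TRUE)
  })
  se <- stats::sd(bds) / sqrt(length(bds))
  expect_lt(abs(mean(bds) - 1), 3 * se + 0.05)
})

test_that("disease diversity counts distinct neighbor classes", {
  dcl <- stats::setNames(c("c1", "c1", "c2", "c3"), paste0("d", 1:4))
  net <- toy_network(c("d1", "d2", "d3", "d4", "d1"),
                     c("s1", "s1", "s2", "s2", "s2"),
                     disease_class = dcl)
  div <- disease_diversity_table(net, n_total_classes = 18)
  expect_equal(div$diversity[div$subpathway_id == "s1"], 1 / 18)
  expect_equal(div$n_classes_hit[div$subpathway_id == "s2"], 3)
  # full span -> 1.0
  div3 <- disease_diversity_table(net, n_total_classes = 3)
  expect_equal(div3$diversity[div3$subpathway_id == "s2"], 1)
  expect_true(all(div$n_classes_hit <= div$degree))

  # adding an edge never decreases a subpathway's diversity
  net2 <- toy_network(c("d1", "d2", "d3", "d4", "d1", "d3"),
                      c("s1", "s1", "s2", "s2", "s2", "s1"),
                      disease_class = dcl)
  div2 <- disease_diversity_table(net2, n_total_classes = 18)
  expect_gte(div2$diversity[div2$subpathway_id == "s1"],
             div$diversity[div$subpathway_id == "s1"])
})

test_that("hierarchical clustering uses L1 complete linkage with stable leaves", {
  # d1 and d2 identical rows -> first merge at height 0
  net <- toy_network(c("d1", "d2", "d3", "d1", "d2"),
                     c("s1", "s1", "s2", "s3", "s3"))
  hc <- hierarchical_cluster(net)
  first <- sort(hc$row_hclust$labels[-hc$row_hclust$merge[1, ]])
  expect_equal(first, c("d1", "d2"))
  expect_equal(hc$row_hclust$height[1], 0)

  # hand-computed L1 distances on rows d1=(1,0,1), d2=(1,0,1), d3=(0,1,0):
  # d(d1,d2)=0, d(d1,d3)=d(d2,d3)=3; complete linkage merges at heights 0, 3
  inc <- hc$incidence
  expect_equal(unname(inc["d1", ]), c(1L, 0L, 1L))
  expect_equal(hc$row_hclust$height, c(0, 3))
  # leaf orders are permutations of the node sets
  expect_setequal(hc$row_order, names(net$disease_class))
  expect_setequal(hc$col_order, names(net$subpathway_class))
  # Newick strings parse back to trees with the right tips
  tr <- ape::read.tree(text = hc$row_newick)
  expect_setequal(tr$tip.label, names(net$disease_class))
})

test_that("clustering output writes a CDT-compatible ordered matrix", {
  net <- toy_network(c("d1", "d2", "d3"), c("s1", "s2", "s1"))
  hc <- hierarchical_cluster(net)
  f <- withr::local_tempfile(fileext = ".cdt")
  write_cdt(hc, f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(back$ID, hc$row_order)
  expect_equal(names(back)[-1], hc$col_order)
})
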