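#' One-mode projection of the bipartite network
#'
#' Projects the network onto one side: two nodes of that side are adjacent
#' iff they share at least `min_shared` neighbors on the other side. The
#' projection is unweighted and keeps every node of the chosen side (also
#' those left isolated by the threshold).
#'
#' @param net A `subpathway_network`.
#' @param side `"disease"` or `"subpathway"`.
#' @param min_shared Minimum number of shared neighbors (default 1).
#' @return A `projection_graph`: list with `graph` (undirected simple
#'   `igraph`), `node_class` (named character) and `side`.
#' @export
one_mode_projection <- function(net, side = c("disease", "subpathway"),
                                min_shared = 1) {
  side <- match.arg(side)
  stopifnot(inherits(net, "subpathway_network"), min_shared >= 1)
  if (nrow(net$edges) == 0) stop("cannot project an empty network")
  classes <- if (side == "disease") net$disease_class else net$subpathway_class
  own <- if (side == "disease") "disease_id" else "subpathway_id"
  other <- if (side == "disease") "subpathway_id" else "disease_id"
  ids <- names(classes)
  nbr <- split(net$edges[[other]], factor(net$edges[[own]], levels = ids))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (length(ids) >= 2) {
    prs <- utils::combn(ids, 2)
    shared <- vapply(seq_len(ncol(prs)), function(j) {
      length(intersect(nbr[[prs[1, j]]], nbr[[prs[2, j]]]))
    }, integer(1))
    keep <- shared >= min_shared
    if (any(keep)) g <- igraph::add_edges(g, as.vector(prs[, keep, drop = FALSE]))
  }
  structure(list(graph = g, node_class = classes, side = side),
            class = "projection_graph")
}

proj_edge_matrix <- function(proj) {
  el <- igraph::as_edgelist(proj$graph, names = TRUE)
  if (!is.matrix(el)) el <- matrix(el, ncol = 2)
  el
}

count_class_edges <- function(edge_mat, members) {
  in1 <- edge_mat[, 1] %in% members
  in2 <- edge_mat[, 2] %in% members
  c(m11 = sum(in1 & in2), m10 = sum(xor(in1, in2)))
}

#' Bipartite dyadicity and heterophilicity of one class
#'
#' Class-clustering statistics on a one-mode projection of the bipartite
#' network. For a class with `n1` members in a projection with `N` nodes
#' and `M` edges, `m11` counts within-class edges and `m10` class-to-outside
#' edges. Dyadicity `BD = m11/e11` and heterophilicity `BH = m10/e10`
#' compare them to their expectations under random placement of the class
#' labels. `BD > 1` means the class's members connect among themselves more
#' than chance; `BH < 1` means they avoid outside connections. `BD > BH`
#' indicates a clustering tendency.
#'
#' Two expectation models are offered. Analytic: with mean connection
#' probability `p = 2M/(N(N-1))`, `e11 = p * n1(n1-1)/2` and
#' `e10 = p * n1(N-n1)`. Permutation: `e11`, `e10` are the means of `m11`,
#' `m10` over `n_perm` uniform relabelings of the node classes (class sizes
#' preserved), which conditions on the projection's actual degree structure.
#'
#' @param proj A `projection_graph`.
#' @param class_label The class to score.
#' @param mode `"analytic"` or `"permutation"`.
#' @param n_perm Number of relabelings in permutation mode.
#' @param seed Seed for permutation mode.
#' @return One-row data frame: `class_label`, `n1`, `m11`, `m10`, `e11`,
#'   `e10`, `BD`, `BH`.
#' @export
bd_bh <- function(proj, class_label, mode = c("analytic", "permutation"),
                  n_perm = 1000, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(proj, "projection_graph"))
  members <- names(proj$node_class)[!is.na(proj$node_class) &
                                      proj$node_class == class_label]
  n1 <- length(members)
  N <- igraph::vcount(proj$graph)
  M <- igraph::ecount(proj$graph)
  if (n1 == 0) stop("class not present in projection: ", class_label)
  el <- proj_edge_matrix(proj)
  obs <- count_class_edges(el, members)
  if (mode == "analytic") {
    p_bar <- if (N >= 2) 2 * M / (N * (N - 1)) else 0
    e11 <- p_bar * n1 * (n1 - 1) / 2
    e10 <- p_bar * n1 * (N - n1)
  } else {
    nodes <- names(proj$node_class)
    set.seed(seed)
    perm <- matrix(0, n_perm, 2)
    for (b in seq_len(n_perm)) {
      perm[b, ] <- count_class_edges(el, sample(nodes, n1))
    }
    e11 <- mean(perm[, 1])
    e10 <- mean(perm[, 2])
  }
  if (e11 <= 0 || e10 <= 0) {
    stop("BD/BH undefined for class '", class_label,
         "' (e11=", signif(e11, 3), ", e10=", signif(e10, 3), ")")
  }
  data.frame(class_label = class_label, n1 = n1,
             m11 = unname(obs["m11"]), m10 = unname(obs["m10"]),
             e11 = e11, e10 = e10,
             BD = unname(obs["m11"]) / e11, BH = unname(obs["m10"]) / e10,
             stringsAsFactors = FALSE)
}

#' BD/BH table for every class on one side of the network
#'
#' Projects the network, scores each class present via [bd_bh()], and
#' appends the unweighted arithmetic means of BD and BH over the classes
#' for which both are defined (classes are the units, not nodes).
#'
#' @inheritParams one_mode_projection
#' @inheritParams bd_bh
#' @return List with `per_class` (data frame, one row per class; `NA`
#'   statistics for undefined classes) and `mean_BD`, `mean_BH`.
#' @export
class_table <- function(net, side = c("disease", "subpathway"),
                        mode = c("analytic", "permutation"),
                        n_perm = 1000, seed = 1, min_shared = 1) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  proj <- one_mode_projection(net, side, min_shared)
  if (any(is.na(proj$node_class))) {
    stop("every ", side, " node needs a class label for class_table")
  }
  labels <- sort(unique(unname(proj$node_class)))
  rows <- lapply(labels, function(lb) {
    tryCatch(bd_bh(proj, lb, mode, n_perm, seed),
             error = function(e) {
               message("class '", lb, "' undefined: ", conditionMessage(e))
               data.frame(class_label = lb,
                          n1 = sum(proj$node_class == lb, na.rm = TRUE),
                          m11 = NA_integer_, m10 = NA_integer_,
                          e11 = NA_real_, e10 = NA_real_,
                          BD = NA_real_, BH = NA_real_,
                          stringsAsFactors = FALSE)
             })
  })
  per_class <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ok <- stats::complete.cases(per_class[, c("BD", "BH")])
  list(per_class = per_class,
       mean_BD = mean(per_class$BD[ok]),
       mean_BH = mean(per_class$BH[ok]))
}

#' Disease diversity of each subpathway
#'
#' For every subpathway node, the number of distinct disease classes among
#' its network neighbors divided by the total number of disease classes.
#' A subpathway causing many diseases that all belong to one class is less
#' "diverse" than one whose few diseases span several classes.
#'
#' @param net A `subpathway_network` with disease class labels.
#' @param n_total_classes Total number of disease classes in the
#'   classification (default: number of distinct classes present).
#' @return Data frame: `subpathway_id`, `degree`, `n_classes_hit`,
#'   `diversity`.
#' @export
disease_diversity_table <- function(net, n_total_classes = NULL) {
  stopifnot(inherits(net, "subpathway_network"))
  if (is.null(n_total_classes)) {
    n_total_classes <- length(unique(stats::na.omit(net$disease_class)))
  }
  stopifnot(n_total_classes >= 1)
  s_ids <- names(net$subpathway_class)
  nbr <- split(net$edges$disease_id,
               factor(net$edges$subpathway_id, levels = s_ids))
  n_hit <- vapply(nbr, function(ds) {
    length(unique(stats::na.omit(net$disease_class[ds])))
  }, integer(1))
  data.frame(subpathway_id = s_ids,
             degree = lengths(nbr),
             n_classes_hit = unname(n_hit),
             diversity = unname(n_hit) / n_total_classes,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hierarchical clustering of the network incidence matrix
#'
#' Builds the binary disease x subpathway incidence matrix (rows and
#' columns pre-sorted by node ID so ties break deterministically), computes
#' city-block (L1, "manhattan") pairwise distances on each axis, and
#' agglomerates with complete linkage. Both dendrograms and the reordered
#' matrix are returned; Newick strings allow export to tree viewers.
#'
#' @param net A `subpathway_network` with at least 2 nodes on each side.
#' @return List with `incidence` (binary matrix in original sorted order),
#'   `row_hclust`, `col_hclust` (`hclust` objects for diseases and
#'   subpathways), `row_order`, `col_order` (leaf-ordered node IDs) and
#'   `row_newick`, `col_newick`.
#' @export
hierarchical_cluster <- function(net) {
  stopifnot(inherits(net, "subpathway_network"), nrow(net$edges) > 0)
  d_ids <- names(net$disease_class)
  s_ids <- names(net$subpathway_class)
  inc <- matrix(0L, length(d_ids), length(s_ids),
                dimnames = list(d_ids, s_ids))
  inc[cbind(net$edges$disease_id, net$edges$subpathway_id)] <- 1L
  cluster_axis <- function(m) {
    if (nrow(m) < 2) return(NULL)
    stats::hclust(stats::dist(m, method = "manhattan"), method = "complete")
  }
  rh <- cluster_axis(inc)
  ch <- cluster_axis(t(inc))
  list(
    incidence = inc,
    row_hclust = rh, col_hclust = ch,
    row_order = if (is.null(rh)) d_ids else rh$labels[rh$order],
    col_order = if (is.null(ch)) s_ids else ch$labels[ch$order],
    row_newick = if (is.null(rh)) NA_character_ else
      ape::write.tree(ape::as.phylo(rh)),
    col_newick = if (is.null(ch)) NA_character_ else
      ape::write.tree(ape::as.phylo(ch))
  )
}

#' Write clustering results in a CDT-compatible layout
#'
#' Tab-delimited ordered matrix readable by heat-map viewers: first column
#' the disease IDs in dendrogram leaf order, remaining columns the
#' subpathways in leaf order, cells the 0/1 incidence.
#'
#' @param clust Result of [hierarchical_cluster()].
#' @param path Output path for the matrix; the two Newick trees are written
#'   alongside with suffixes `.rows.nwk` / `.cols.nwk` when defined.
#' @export
write_cdt <- function(clust, path) {
  m <- clust$incidence[clust$row_order, clust$col_order, drop = FALSE]
  out <- data.frame(ID = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.na(clust$row_newick)) {
    writeLines(clust$row_newick, paste0(path, ".rows.nwk"))
  }
  if (!is.na(clust$col_newick)) {
    writeLines(clust$col_newick, paste0(path, ".cols.nwk"))
  }
  invisible(path)
}
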