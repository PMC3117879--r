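#' k-th graph power
#'
#' Returns a graph on the same vertex set in which two distinct vertices are
#' adjacent iff their shortest-path distance in `g` is at most `k`.
#' Disconnected pairs (infinite distance) are never adjacent.
#'
#' @param g An undirected `igraph`.
#' @param k Positive integer distance cutoff.
#' @return An undirected simple `igraph` on the same (named) vertices.
#' @export
graph_power <- function(g, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != floor(k)) {
    stop("k must be a positive integer")
  }
  n <- igraph::vcount(g)
  gp <- igraph::make_empty_graph(n = 0, directed = FALSE)
  gp <- igraph::add_vertices(gp, n, name = igraph::V(g)$name)
  if (n >= 2) {
    d <- igraph::distances(g)
    idx <- which(upper.tri(d) & is.finite(d) & d <= k & d > 0, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      nm <- igraph::V(g)$name
      gp <- igraph::add_edges(gp, rbind(nm[idx[, 1]], nm[idx[, 2]]))
    }
  }
  for (a in names(igraph::graph_attr(g))) {
    igraph::graph_attr(gp, a) <- igraph::graph_attr(g, a)
  }
  gp
}

#' Enumerate maximal cliques in canonical order
#'
#' Wraps Bron-Kerbosch maximal-clique enumeration and fixes a deterministic
#' output order: decreasing clique size, ties broken lexicographically on
#' the sorted vertex names. This order is what assigns subpathway indices,
#' so it is part of the mining contract.
#'
#' @param g An undirected `igraph` with named vertices.
#' @return List of character vectors (sorted vertex names), one per maximal
#'   clique.
#' @export
enumerate_maximal_cliques <- function(g) {
  if (igraph::vcount(g) == 0) return(list())
  cl <- igraph::max_cliques(g)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  key <- vapply(cl, paste, character(1), collapse = ";")
  ord <- order(-lengths(cl), key, method = "radix")
  cl[ord]
}

#' Mine k-clique subpathways from one enzyme graph
#'
#' A subpathway is a maximal set of enzymes whose pairwise shortest-path
#' distance in the original pathway graph is at most `k` (k-clique in the
#' distance sense: distances are measured in the whole graph, not inside
#' the induced subgraph as a k-club would). These sets are exactly the
#' maximal cliques of the k-th graph power. Each subpathway inherits the
#' pathway's class label and receives an ID `"<pathway_id>_<i>"` with `i`
#' assigned in canonical clique order; its gene set is the union of genes
#' annotated to its enzymes.
#'
#' @param g Enzyme graph from [build_enzyme_graph()].
#' @param k Positive integer distance parameter (3 is the usual working
#'   scale; 4 gives coarser subpathways).
#' @param ann A `gene_annotation_map`, or `NULL` for enzyme-only mining.
#' @param min_enzymes Minimum number of enzymes a subpathway must contain
#'   (default 1, i.e. no filtering).
#' @return A data frame with columns `subpathway_id`, `pathway_id`,
#'   `class_label`, `n_enzymes`, `n_genes` and list-columns `enzymes`,
#'   `genes`.
#' @export
mine_subpathways <- function(g, k = 3, ann = NULL, min_enzymes = 1) {
  stopifnot(min_enzymes >= 1)
  pid <- igraph::graph_attr(g, "pathway_id")
  if (is.null(pid)) pid <- ""
  cls <- igraph::graph_attr(g, "class_label")
  if (is.null(cls)) cls <- "unclassified"
  cliques <- enumerate_maximal_cliques(graph_power(g, k))
  cliques <- cliques[lengths(cliques) >= min_enzymes]
  genes <- lapply(cliques, function(ecs) {
    if (is.null(ann)) character(0) else genes_for_enzymes(ann, ecs)
  })
  data.frame(
    subpathway_id = if (length(cliques)) paste0(pid, "_", seq_along(cliques)) else character(0),
    pathway_id = rep(pid, length(cliques)),
    class_label = rep(cls, length(cliques)),
    n_enzymes = lengths(cliques),
    n_genes = lengths(genes),
    enzymes = I(cliques),
    genes = I(genes),
    stringsAsFactors = FALSE
  )
}

#' Mine subpathways across a pathway collection
#'
#' @param pathways List of `pathway_definition` objects with unique IDs.
#' @param k Distance parameter, as in [mine_subpathways()].
#' @param ann A `gene_annotation_map` shared by the collection.
#' @param currency_blacklist Compound IDs excluded from edge formation.
#' @param min_enzymes Minimum subpathway size.
#' @return Row-bound subpathway table; IDs are globally unique because each
#'   pathway ID is.
#' @export
mine_collection <- function(pathways, k = 3, ann = NULL,
                            currency_blacklist = character(0),
                            min_enzymes = 1) {
  ids <- vapply(pathways, function(p) p$pathway_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate pathway_id in collection: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  empty <- mine_subpathways(named_empty_graph(), k = k, ann = ann)
  tabs <- lapply(pathways, function(p) {
    mine_subpathways(build_enzyme_graph(p, currency_blacklist),
                     k = k, ann = ann, min_enzymes = min_enzymes)
  })
  do.call(rbind, c(list(empty), tabs, list(make.row.names = FALSE)))
}

named_empty_graph <- function() {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  igraph::set_vertex_attr(g, "name", value = character(0))
}

#' Write / read the subpathway table
#'
#' TSV with columns `subpathway_id`, `pathway_id`, `class_label`,
#' `enzymes`, `genes`; the two list columns are `';'`-joined.
#'
#' @param subpathways Subpathway table from [mine_collection()].
#' @param path Output file path.
#' @export
write_subpathway_table <- function(subpathways, path) {
  out <- data.frame(
    subpathway_id = subpathways$subpathway_id,
    pathway_id = subpathways$pathway_id,
    class_label = subpathways$class_label,
    enzymes = vapply(subpathways$enzymes, paste, character(1), collapse = ";"),
    genes = vapply(subpathways$genes, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subpathway_table
#' @export
read_subpathway_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  split_semi <- function(v) lapply(strsplit(v, ";", fixed = TRUE),
                                   function(x) x[nzchar(x)])
  enz <- split_semi(tab$enzymes)
  gen <- split_semi(tab$genes)
  data.frame(
    subpathway_id = tab$subpathway_id,
    pathway_id = tab$pathway_id,
    class_label = tab$class_label,
    n_enzymes = lengths(enz),
    n_genes = lengths(gen),
    enzymes = I(enz),
    genes = I(gen),
    stringsAsFactors = FALSE
  )
}
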