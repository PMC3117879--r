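# Brute-force oracles, independent of the igraph-based implementation paths.

# logical adjacency matrix of an undirected igraph
adj_of <- function(g) {
  nm <- igraph::V(g)$name
  n <- length(nm)
  a <- matrix(FALSE, n, n, dimnames = list(nm, nm))
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) > 0) {
    a[el] <- TRUE
    a[el[, 2:1, drop = FALSE]] <- TRUE
  }
  a
}

# all-pairs shortest paths by level-by-level BFS on the adjacency matrix
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n, dimnames = dimnames(a))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    lev <- 0
    while (length(frontier) > 0) {
      lev <- lev + 1
      nxt <- which(colSums(a[frontier, , drop = FALSE]) > 0 & !is.finite(dist))
      dist[nxt] <- lev
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  d
}

# maximal sets with pairwise distance <= k, by exhaustive subset enumeration
# (n <= ~12); maximality checked by single-vertex extendability
brute_force_kcliques <- function(a, k) {
  d <- oracle_distances(a)
  n <- nrow(a)
  nm <- rownames(a)
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    sub <- d[idx, idx, drop = FALSE]
    if (any(sub > k)) next
    extendable <- FALSE
    for (v in setdiff(seq_len(n), idx)) {
      if (all(d[v, idx] <= k)) { extendable <- TRUE; break }
    }
    if (!extendable) out[[length(out) + 1]] <- sort(nm[idx])
  }
  unique(out)
}

brute_force_max_cliques <- function(a) {
  diag(a) <- TRUE  # so single vertices count as cliques of themselves
  n <- nrow(a)
  nm <- rownames(a)
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!all(a[idx, idx])) next
    extendable <- FALSE
    for (v in setdiff(seq_len(n), idx)) {
      if (all(a[v, idx])) { extendable <- TRUE; break }
    }
    if (!extendable) out[[length(out) + 1]] <- sort(nm[idx])
  }
  unique(out)
}

canon_sets <- function(sets) {
  sets <- lapply(unname(unclass(sets)), as.character)
  keys <- vapply(sets, paste, character(1), collapse = ";")
  sets[order(keys)]
}

# P(X >= x) by enumerating every possible draw of n_d from N_bg elements
# of which the first m are "successes"
enum_hyper_pvalue <- function(x, n_d, m, N_bg) {
  if (x == 0) return(1)
  draws <- utils::combn(N_bg, n_d)
  mean(colSums(draws <= m) >= x)
}

# random undirected graph with named vertices (for oracle comparisons)
random_named_graph <- function(n, p, pathway_id = "path:test") {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("e%02d", seq_len(n))
  igraph::graph_attr(g, "pathway_id") <- pathway_id
  igraph::graph_attr(g, "class_label") <- "test class"
  g
}

# named graph from an explicit edge list (character vector pairs)
named_graph <- function(nodes, edges = character(0),
                        pathway_id = "path:test") {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  igraph::graph_attr(g, "pathway_id") <- pathway_id
  igraph::graph_attr(g, "class_label") <- "test class"
  g
}

# small bipartite network straight from an edge data frame
toy_network <- function(d, s, p = NULL, disease_class = NULL,
                        subpathway_class = NULL) {
  edges <- data.frame(disease_id = d, subpathway_id = s,
                      p_value = if (is.null(p)) rep(0.001, length(d)) else p,
                      stringsAsFactors = FALSE)
  net <- build_network(edges)
  if (!is.null(disease_class)) {
    net$disease_class[names(disease_class)] <- disease_class
  }
  if (!is.null(subpathway_class)) {
    net$subpathway_class[names(subpathway_class)] <- subpathway_class
  }
  net
}

# three-reaction linear chain pathway: S1 -E1-> C1 -E2-> C2 -E3-> P
chain_pathway <- function(reversible = FALSE) {
  subpathnet:::new_pathway_definition(
    "path:chain", "chain", "test class",
    list(
      list(reaction_id = "R1", substrates = "S1", products = "C1",
           enzymes = "1.1.1.1", reversible = reversible),
      list(reaction_id = "R2", substrates = "C1", products = "C2",
           enzymes = "2.2.2.2", reversible = reversible),
      list(reaction_id = "R3", substrates = "C2", products = "P1",
           enzymes = "3.3.3.3", reversible = reversible)
    ),
    c("1.1.1.1", "2.2.2.2", "3.3.3.3"))
}

edge_key <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0) return(character(0))
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}

small_design <- function(...) {
  args <- utils::modifyList(
    list(n_pathways = 8, enzymes_per_pathway = c(5, 10),
         n_background_genes = 400, n_diseases = 24,
         n_disease_classes = 6, n_planted = 12,
         genes_per_disease = c(8, 20), n_tissues = 12),
    list(...))
  do.call(simulation_design, args)
}
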