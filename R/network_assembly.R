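#' Assemble the bipartite disease-subpathway network
#'
#' Keeps the significant enrichment pairs as edges. Nodes are exactly the
#' endpoints of retained edges, so every node has degree >= 1; the network
#' is strictly bipartite by construction.
#'
#' @param results Enrichment table ([enrich_all()]), or any data frame with
#'   `disease_id`, `subpathway_id`, `p_value` and optionally `significant`
#'   (rows are taken as-is when the column is absent, e.g. when loading a
#'   published edge list).
#' @param diseases Optional disease table supplying `disease_class` labels.
#' @param subpathways Optional subpathway table supplying `class_label`s.
#' @return A `subpathway_network`: list with `edges` (data frame
#'   `disease_id`, `subpathway_id`, `p_value`), `disease_class` and
#'   `subpathway_class` (named character vectors, `NA` where unknown).
#' @export
build_network <- function(results, diseases = NULL, subpathways = NULL) {
  edges <- if ("significant" %in% names(results)) {
    results[which(results$significant), c("disease_id", "subpathway_id", "p_value")]
  } else {
    results[, c("disease_id", "subpathway_id", "p_value")]
  }
  edges <- edges[order(edges$disease_id, edges$subpathway_id,
                       method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  d_ids <- sort(unique(edges$disease_id))
  s_ids <- sort(unique(edges$subpathway_id))
  dcl <- stats::setNames(rep(NA_character_, length(d_ids)), d_ids)
  scl <- stats::setNames(rep(NA_character_, length(s_ids)), s_ids)
  if (!is.null(diseases)) {
    hit <- intersect(d_ids, diseases$disease_id)
    dcl[hit] <- diseases$disease_class[match(hit, diseases$disease_id)]
  }
  if (!is.null(subpathways)) {
    hit <- intersect(s_ids, subpathways$subpathway_id)
    scl[hit] <- subpathways$class_label[match(hit, subpathways$subpathway_id)]
  }
  structure(list(edges = edges, disease_class = dcl, subpathway_class = scl),
            class = "subpathway_network")
}

#' @export
print.subpathway_network <- function(x, ...) {
  cat(sprintf("<subpathway_network> %d diseases, %d subpathways, %d edges\n",
              length(x$disease_class), length(x$subpathway_class),
              nrow(x$edges)))
  invisible(x)
}

#' Convert a subpathway network to a bipartite igraph
#'
#' Disease vertices get `type = FALSE`, subpathway vertices `type = TRUE`;
#' class labels are carried as the `node_class` vertex attribute and
#' enrichment P-values as the `p_value` edge attribute.
#'
#' @param net A `subpathway_network`.
#' @return A bipartite `igraph`.
#' @export
network_igraph <- function(net) {
  stopifnot(inherits(net, "subpathway_network"))
  d_ids <- names(net$disease_class)
  s_ids <- names(net$subpathway_class)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(d_ids), name = d_ids, type = FALSE,
                            node_class = unname(net$disease_class))
  g <- igraph::add_vertices(g, length(s_ids), name = s_ids, type = TRUE,
                            node_class = unname(net$subpathway_class))
  if (nrow(net$edges) > 0) {
    g <- igraph::add_edges(g, rbind(net$edges$disease_id,
                                    net$edges$subpathway_id),
                           p_value = net$edges$p_value)
  }
  g
}

#' Degree sequences of a subpathway network
#'
#' @param net A `subpathway_network`.
#' @param side `"disease"` or `"subpathway"`.
#' @return Named integer vector of node degrees on that side.
#' @export
network_degrees <- function(net, side = c("disease", "subpathway")) {
  side <- match.arg(side)
  ids <- names(if (side == "disease") net$disease_class else net$subpathway_class)
  col <- if (side == "disease") "disease_id" else "subpathway_id"
  tab <- table(factor(net$edges[[col]], levels = ids))
  stats::setNames(as.integer(tab), ids)
}

#' Global summary of a subpathway network
#'
#' @param net A `subpathway_network`.
#' @return A `network_summary`: node and edge counts, mean degree per side,
#'   bipartite density (edges / (diseases x subpathways)), size of the
#'   giant connected component, and the two degree sequences.
#' @export
summarize_network <- function(net) {
  dd <- network_degrees(net, "disease")
  sd_ <- network_degrees(net, "subpathway")
  n_d <- length(dd); n_s <- length(sd_); n_e <- nrow(net$edges)
  giant <- if (n_d + n_s == 0) 0L else {
    max(igraph::components(network_igraph(net))$csize)
  }
  structure(list(
    n_diseases = n_d, n_subpathways = n_s, n_edges = n_e,
    mean_disease_degree = if (n_d) mean(dd) else NA_real_,
    mean_subpathway_degree = if (n_s) mean(sd_) else NA_real_,
    density = if (n_d && n_s) n_e / (n_d * n_s) else NA_real_,
    giant_component_size = as.integer(giant),
    disease_degrees = dd, subpathway_degrees = sd_
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<network_summary> %d diseases, %d subpathways, %d edges\n",
    "  mean degree: disease %.2f, subpathway %.2f; density %.4f; giant component %d\n"),
    x$n_diseases, x$n_subpathways, x$n_edges,
    x$mean_disease_degree, x$mean_subpathway_degree, x$density,
    x$giant_component_size))
  invisible(x)
}

#' Degree-distribution breadth of one side of the network
#'
#' Operationalizes "breadth" of a degree distribution as its coefficient
#' of variation (sd/mean); a regular degree sequence scores 0 and a
#' fat-tailed one scores high. The variance is available as an
#' alternative statistic.
#'
#' @param summary A `network_summary`.
#' @param side `"disease"` or `"subpathway"`.
#' @param statistic `"cv"` (default) or `"var"`.
#' @return The breadth statistic (numeric scalar).
#' @export
degree_breadth_statistic <- function(summary, side = c("disease", "subpathway"),
                                     statistic = c("cv", "var")) {
  side <- match.arg(side)
  statistic <- match.arg(statistic)
  deg <- if (side == "disease") summary$disease_degrees else summary$subpathway_degrees
  if (length(deg) < 2) stop("degree-breadth needs >= 2 nodes on the ", side, " side")
  switch(statistic,
         cv = stats::sd(deg) / mean(deg),
         var = stats::var(deg))
}

#' Empirical P-value against a null sample
#'
#' Add-one estimator `(1 + #extreme) / (1 + n)`, which never returns zero.
#'
#' @param observed Observed statistic.
#' @param null_samples Numeric vector of null replicates.
#' @param side `"greater"` counts samples `>= observed`, `"less"` samples
#'   `<= observed`.
#' @return Empirical P-value in (0, 1].
#' @export
empirical_pvalue <- function(observed, null_samples,
                             side = c("greater", "less")) {
  side <- match.arg(side)
  if (length(null_samples) == 0) stop("empty null sample")
  extreme <- if (side == "greater") sum(null_samples >= observed)
             else sum(null_samples <= observed)
  (1 + extreme) / (1 + length(null_samples))
}

#' Null ensemble of networks from resampled disease gene sets
#'
#' The null model keeps every disease's gene-set size and the subpathway
#' collection fixed, but replaces each disease's genes with a uniform
#' random draw from the background; the whole pipeline (enrichment at the
#' same `alpha`, network assembly, summary) is rerun per replicate. This
#' destroys any true disease-subpathway association while preserving the
#' test multiplicity, so the observed network's density, giant component
#' and degree breadth can be referred to the ensemble via
#' [empirical_pvalue()].
#'
#' @param diseases Disease gene-set table (sizes are reused).
#' @param subpathways Subpathway table.
#' @param background Gene universe.
#' @param alpha Enrichment cutoff.
#' @param R Number of replicates (1000 matches a full-scale analysis; 100-200
#'   is plenty for desk-scale checks).
#' @param seed Integer seed; the ensemble is a pure function of it.
#' @return A `null_ensemble`: list with `n_replicates`, `seed`, `summaries`
#'   (list of `network_summary`) and `samples`, a data frame of per-replicate
#'   statistics (`n_edges`, `density`, `universe_density`,
#'   `giant_component_size`, `disease_breadth`, `subpathway_breadth`).
#'   `density` is the bipartite density over the replicate's own retained
#'   nodes (isolated nodes drop out, so sparse replicates can paradoxically
#'   score high); `universe_density` divides the edge count by the fixed
#'   number of tested pairs (all input diseases x all subpathways), which is
#'   the statistic comparable across replicates and with the observed
#'   network.
#' @export
random_null_ensemble <- function(diseases, subpathways, background,
                                 alpha = 0.01, R = 200, seed = 1) {
  if (R < 1) stop("R must be >= 1")
  summaries <- vector("list", R)
  n_pairs <- nrow(diseases) * nrow(subpathways)
  stats_df <- data.frame(n_edges = integer(R), density = numeric(R),
                         universe_density = numeric(R),
                         giant_component_size = integer(R),
                         disease_breadth = numeric(R),
                         subpathway_breadth = numeric(R))
  set.seed(seed)
  for (r in seq_len(R)) {
    null_d <- diseases
    null_d$genes <- I(lapply(lengths(diseases$genes), function(sz) {
      sample(background, min(sz, length(background)))
    }))
    res <- enrich_all(null_d, subpathways, background, alpha = alpha)
    net <- build_network(res, diseases = null_d, subpathways = subpathways)
    s <- summarize_network(net)
    summaries[[r]] <- s
    stats_df$n_edges[r] <- s$n_edges
    stats_df$density[r] <- ifelse(is.na(s$density), 0, s$density)
    stats_df$universe_density[r] <- s$n_edges / n_pairs
    stats_df$giant_component_size[r] <- s$giant_component_size
    stats_df$disease_breadth[r] <-
      if (s$n_diseases >= 2) degree_breadth_statistic(s, "disease") else NA_real_
    stats_df$subpathway_breadth[r] <-
      if (s$n_subpathways >= 2) degree_breadth_statistic(s, "subpathway") else NA_real_
  }
  structure(list(n_replicates = R, seed = seed, summaries = summaries,
                 samples = stats_df),
            class = "null_ensemble")
}

#' Write / read the network edge list
#'
#' TSV with columns `disease_id`, `subpathway_id`, `p_value`, in the
#' network's canonical (disease, subpathway) order, so write-then-read
#' round-trips exactly.
#'
#' @param net A `subpathway_network`.
#' @param path File path.
#' @export
write_network_edges <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_edges
#' @export
read_network_edges <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(disease_id = "character",
                                   subpathway_id = "character",
                                   p_value = "numeric"))
}

#' Export a network for visualization tools
#'
#' @param net A `subpathway_network`.
#' @param path Output path (`.graphml` or `.sif`).
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(network_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_sif <- function(net, path) {
  lines <- sprintf("%s\tenriched_in\t%s", net$edges$disease_id,
                   net$edges$subpathway_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write a network summary as JSON
#'
#' @param summary A `network_summary`.
#' @param path Output path.
#' @export
write_summary_json <- function(summary, path) {
  x <- unclass(summary)
  x$disease_degrees <- as.list(x$disease_degrees)
  x$subpathway_degrees <- as.list(x$subpathway_degrees)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
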