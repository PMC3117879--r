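#' Parse a KGML pathway file
#'
#' Reads a KEGG Markup Language (KGML) XML file and extracts the pathway's
#' reaction list and enzyme set. Enzymes are taken from `entry` elements of
#' type `"enzyme"`; each such entry may reference one or more reactions
#' through its `reaction` attribute. Reactions are read from `reaction`
#' elements, with substrate and product compound IDs taken from their child
#' elements and reversibility from the reaction `type` attribute
#' (`"reversible"` vs `"irreversible"`).
#'
#' @param file_path Path to a KGML XML file.
#' @param class_label Metabolism class of the pathway (e.g.
#'   `"lipid metabolism"`); carried through to mined subpathways.
#' @return A `pathway_definition` object: a list with elements
#'   `pathway_id`, `name`, `class_label`, `reactions` (a list of reaction
#'   records, each with `reaction_id`, `substrates`, `products`, `enzymes`,
#'   `reversible`) and `enzymes` (character vector of EC numbers).
#' @details A file with no enzyme entries yields an empty definition with a
#'   warning rather than an error. Malformed XML raises the parser's error,
#'   which names the offending line.
#' @export
parse_kgml <- function(file_path, class_label = "unclassified") {
  doc <- xml2::read_xml(file_path)
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) stop("not a KGML document (no <pathway> root): ", file_path)
  pathway_id <- xml2::xml_attr(root, "name")
  if (is.na(pathway_id)) pathway_id <- ""
  pathway_name <- xml2::xml_attr(root, "title")
  if (is.na(pathway_name)) pathway_name <- pathway_id

  entries <- xml2::xml_find_all(doc, "//entry[@type='enzyme']")
  # reaction name -> EC numbers carried by entries referencing it
  rx2ec <- list()
  all_ecs <- character(0)
  for (e in entries) {
    ecs <- strip_kegg_prefix(strsplit(xml2::xml_attr(e, "name"), "\\s+")[[1]])
    ecs <- ecs[nzchar(ecs)]
    all_ecs <- c(all_ecs, ecs)
    rx_ref <- xml2::xml_attr(e, "reaction")
    if (!is.na(rx_ref)) {
      for (rid in strsplit(rx_ref, "\\s+")[[1]]) {
        rx2ec[[rid]] <- union(rx2ec[[rid]], ecs)
      }
    }
  }

  rx_nodes <- xml2::xml_find_all(doc, "//reaction")
  reactions <- vector("list", length(rx_nodes))
  for (i in seq_along(rx_nodes)) {
    rx <- rx_nodes[[i]]
    rid <- xml2::xml_attr(rx, "name")
    subs <- strip_kegg_prefix(xml2::xml_attr(xml2::xml_find_all(rx, "substrate"), "name"))
    prods <- strip_kegg_prefix(xml2::xml_attr(xml2::xml_find_all(rx, "product"), "name"))
    reactions[[i]] <- list(
      reaction_id = rid,
      substrates = unique(subs),
      products = unique(prods),
      enzymes = sort(unique(rx2ec[[rid]])),
      reversible = identical(xml2::xml_attr(rx, "type"), "reversible")
    )
  }
  # keep only reactions carrying at least one enzyme EC
  reactions <- Filter(function(r) length(r$enzymes) >= 1, reactions)

  if (length(all_ecs) == 0) {
    warning("no enzyme entries in ", file_path, "; returning empty pathway")
  }
  new_pathway_definition(pathway_id, pathway_name, class_label,
                         reactions, sort(unique(all_ecs)))
}

strip_kegg_prefix <- function(x) sub("^(ec:|cpd:|rn:|gl:)", "", x)

new_pathway_definition <- function(pathway_id, name, class_label,
                                   reactions, enzymes) {
  structure(
    list(pathway_id = pathway_id, name = name, class_label = class_label,
         reactions = reactions, enzymes = enzymes),
    class = "pathway_definition"
  )
}

#' @export
print.pathway_definition <- function(x, ...) {
  cat(sprintf("<pathway_definition> %s (%s): %d reactions, %d enzymes\n",
              x$pathway_id, x$class_label, length(x$reactions),
              length(x$enzymes)))
  invisible(x)
}

#' Convert a pathway definition to an undirected enzyme graph
#'
#' Each enzyme (EC number) becomes a node. Two distinct enzymes A and B are
#' joined by an edge iff (i) they are listed on the same reaction, or
#' (ii) some compound outside the currency blacklist is a product of one of
#' A's reactions and a substrate of one of B's reactions (or vice versa).
#' Reversible reactions contribute both orientations, so their substrate and
#' product sets are interchangeable for rule (ii).
#'
#' @param pw A `pathway_definition`.
#' @param currency_blacklist Character vector of compound IDs to ignore when
#'   applying rule (ii) (ubiquitous currency metabolites such as ATP or H2O
#'   otherwise connect nearly everything). Default: none.
#' @return An undirected simple `igraph` with enzyme ECs as vertex names and
#'   a `pathway_id` graph attribute. Enzymes with no edges are retained as
#'   isolated vertices.
#' @export
build_enzyme_graph <- function(pw, currency_blacklist = character(0)) {
  stopifnot(inherits(pw, "pathway_definition"))
  nodes <- pw$enzymes
  edges <- character(0)
  rx <- lapply(pw$reactions, function(r) {
    subs <- setdiff(r$substrates, currency_blacklist)
    prods <- setdiff(r$products, currency_blacklist)
    if (isTRUE(r$reversible)) {
      both <- union(subs, prods)
      list(enzymes = r$enzymes, subs = both, prods = both)
    } else {
      list(enzymes = r$enzymes, subs = subs, prods = prods)
    }
  })
  for (r in rx) {
    # rule (i): co-listed enzymes
    if (length(r$enzymes) >= 2) {
      prs <- utils::combn(sort(r$enzymes), 2)
      edges <- c(edges, as.vector(prs))
    }
  }
  if (length(rx) >= 2) {
    for (i in seq_along(rx)) {
      for (j in seq_along(rx)) {
        if (i == j) next
        # rule (ii): product of reaction i feeds substrate of reaction j
        if (length(intersect(rx[[i]]$prods, rx[[j]]$subs)) > 0) {
          for (a in rx[[i]]$enzymes) for (b in rx[[j]]$enzymes) {
            if (a != b) edges <- c(edges, min(a, b), max(a, b))
          }
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  g <- igraph::simplify(g)
  igraph::graph_attr(g, "pathway_id") <- pw$pathway_id
  igraph::graph_attr(g, "class_label") <- pw$class_label
  g
}

#' Load gene-to-enzyme annotations
#'
#' Reads a two-column tab-delimited table (gene ID, EC number) into a pair
#' of inverse mappings. Lines starting with `#` are ignored; duplicate rows
#' are collapsed; rows with a missing field are dropped with a message
#' reporting the count.
#'
#' @param file_path Path to the TSV file.
#' @return A `gene_annotation_map`: list with `gene2ec` and `ec2gene`, each
#'   a named list of character vectors.
#' @export
load_gene_annotations <- function(file_path) {
  lines <- readLines(file_path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(new_annotation_map(list(), list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, function(p) length(p) >= 2 && nzchar(p[1]) && nzchar(p[2]),
               logical(1))
  if (any(!ok)) {
    message(sum(!ok), " malformed annotation row(s) rejected")
  }
  parts <- parts[ok]
  genes <- vapply(parts, `[`, character(1), 1)
  ecs <- vapply(parts, `[`, character(1), 2)
  annotation_map_from_pairs(genes, ecs)
}

annotation_map_from_pairs <- function(genes, ecs) {
  keep <- !duplicated(paste0(genes, "\r", ecs))
  genes <- genes[keep]; ecs <- ecs[keep]
  g2e <- lapply(split(ecs, genes), function(v) sort(unique(v)))
  e2g <- lapply(split(genes, ecs), function(v) sort(unique(v)))
  new_annotation_map(g2e, e2g)
}

new_annotation_map <- function(g2e, e2g) {
  structure(list(gene2ec = g2e, ec2gene = e2g), class = "gene_annotation_map")
}

#' @export
print.gene_annotation_map <- function(x, ...) {
  cat(sprintf("<gene_annotation_map> %d genes, %d enzymes\n",
              length(x$gene2ec), length(x$ec2gene)))
  invisible(x)
}

#' Genes annotated to a set of enzymes
#'
#' @param ann A `gene_annotation_map`.
#' @param ecs Character vector of EC numbers.
#' @return Sorted character vector of gene IDs annotated to any of `ecs`.
#' @export
genes_for_enzymes <- function(ann, ecs) {
  stopifnot(inherits(ann, "gene_annotation_map"))
  hits <- unlist(ann$ec2gene[intersect(ecs, names(ann$ec2gene))],
                 use.names = FALSE)
  sort(unique(as.character(hits)))
}

#' Read a currency-metabolite blacklist
#'
#' One compound ID per line; `#` comment lines, inline `#` comments and
#' blank lines are skipped. A curated list of common currency metabolites
#' ships with the package:
#' `system.file("extdata", "currency_metabolites.txt", package = "subpathnet")`.
#'
#' @param file_path Path to the list file.
#' @return Character vector of compound IDs.
#' @export
read_compound_blacklist <- function(file_path) {
  lines <- trimws(sub("#.*$", "", readLines(file_path)))
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\\s+"), `[`, character(1), 1)
}
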