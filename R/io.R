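#' Read a GAD-style gene-disease association table
#'
#' Tab-delimited with header columns `disease_id`, `disease_class`,
#' `gene_id` (one association per row). Rows are grouped by disease,
#' duplicate associations collapsed, and per-disease gene counts logged.
#' Lines starting with `#` are skipped.
#'
#' @param path Path to the TSV file.
#' @return Disease gene-set table as from [disease_gene_sets()].
#' @export
read_gad_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = "character")
  need <- c("disease_id", "disease_class", "gene_id")
  missing_col <- setdiff(need, names(tab))
  if (length(missing_col)) {
    stop("GAD table missing column(s): ", paste(missing_col, collapse = ", "))
  }
  if (nrow(tab) == 0) {
    return(disease_gene_sets(character(0), character(0), list()))
  }
  tab <- unique(tab[, need])
  ids <- sort(unique(tab$disease_id))
  genes <- lapply(ids, function(d) tab$gene_id[tab$disease_id == d])
  cls <- tab$disease_class[match(ids, tab$disease_id)]
  message(length(ids), " disease(s), ", nrow(tab), " unique associations")
  disease_gene_sets(ids, cls, genes)
}

#' @rdname read_gad_table
#' @param diseases Disease gene-set table to write.
#' @export
write_gad_table <- function(diseases, path) {
  out <- data.frame(
    disease_id = rep(diseases$disease_id, lengths(diseases$genes)),
    disease_class = rep(diseases$disease_class, lengths(diseases$genes)),
    gene_id = unlist(diseases$genes, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix
#'
#' TSV with a header row of tissue names and gene IDs in the first column.
#'
#' @param path File path.
#' @return Numeric matrix, rows genes, columns tissues.
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_matrix
#' @param expr Matrix to write.
#' @export
write_expression_matrix <- function(expr, path) {
  out <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble and validate a run configuration
#'
#' Accepts a YAML file path or a named list; unknown fields are rejected,
#' defaults are filled in, and the result can be serialized alongside
#' outputs for provenance.
#'
#' @param config YAML path or named list. Recognized fields: input paths
#'   (`kgml_dir`, `pathway_classes`, `gene_annotations`, `gad_table`,
#'   `currency_blacklist`, `expression`, `disease_genes`,
#'   `essential_genes`, `housekeeping_genes`, `tissue_specific_genes`),
#'   parameters (`k`, `alpha`, `null_replicates`, `seed`, `min_shared`,
#'   `bdbh_mode`, `n_bins`, `coexpression_method`, `min_enzymes`) and
#'   `out_dir`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    kgml_dir = NULL, pathway_classes = NULL, gene_annotations = NULL,
    gad_table = NULL, currency_blacklist = NULL, expression = NULL,
    disease_genes = NULL, essential_genes = NULL,
    housekeeping_genes = NULL, tissue_specific_genes = NULL,
    k = 3, alpha = 0.01, null_replicates = 0, seed = 1,
    min_shared = 1, bdbh_mode = "analytic", n_bins = 10,
    coexpression_method = "pearson", min_enzymes = 1,
    out_dir = "subpathnet_out")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  stopifnot(cfg$k >= 1, cfg$alpha > 0, cfg$alpha <= 1,
            cfg$null_replicates >= 0, cfg$n_bins >= 1,
            cfg$bdbh_mode %in% c("analytic", "permutation"),
            cfg$coexpression_method %in% c("pearson", "spearman"))
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline from a configuration
#'
#' Reads every configured input, mines subpathways, runs enrichment,
#' assembles the network, and computes whichever downstream analyses the
#' inputs support (class-structure statistics and clustering always;
#' gene-ratio trends when gene lists are configured; coexpression when an
#' expression matrix is; a null ensemble when `null_replicates > 0`).
#' All result tables are written under `out_dir` together with a run
#' manifest (config, seed, package version).
#'
#' @param config A [run_config()], YAML path, or named list.
#' @return Invisibly, a list of the in-memory results (`subpathways`,
#'   `enrichment`, `network`, `summary`, `class_tables`, `diversity`,
#'   `clustering`, and optionally `profiles`, `trends`, `coexpression`,
#'   `null_ensemble`).
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  if (is.null(cfg$kgml_dir) || is.null(cfg$gene_annotations) ||
      is.null(cfg$gad_table)) {
    stop("config must set kgml_dir, gene_annotations and gad_table")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  classes <- NULL
  if (!is.null(cfg$pathway_classes)) {
    pc <- utils::read.delim(cfg$pathway_classes, stringsAsFactors = FALSE)
    classes <- stats::setNames(pc$class_label, pc$pathway_id)
  }
  files <- sort(list.files(cfg$kgml_dir, pattern = "\\.xml$",
                           full.names = TRUE))
  pathways <- lapply(files, function(f) {
    pw <- parse_kgml(f)
    if (!is.null(classes) && pw$pathway_id %in% names(classes)) {
      pw$class_label <- classes[[pw$pathway_id]]
    }
    pw
  })
  ann <- load_gene_annotations(cfg$gene_annotations)
  blacklist <- if (is.null(cfg$currency_blacklist)) character(0)
               else read_compound_blacklist(cfg$currency_blacklist)
  diseases <- read_gad_table(cfg$gad_table)
  background <- pathway_background(ann)

  subpathways <- mine_collection(pathways, k = cfg$k, ann = ann,
                                 currency_blacklist = blacklist,
                                 min_enzymes = cfg$min_enzymes)
  enr <- enrich_all(diseases, subpathways, background, alpha = cfg$alpha)
  net <- build_network(enr, diseases = diseases, subpathways = subpathways)
  summ <- summarize_network(net)

  res <- list(subpathways = subpathways, enrichment = enr, network = net,
              summary = summ)
  write_subpathway_table(subpathways, file.path(cfg$out_dir, "subpathways.tsv"))
  write_enrichment_table(enr, file.path(cfg$out_dir, "enrichment.tsv"))
  write_network_edges(net, file.path(cfg$out_dir, "network_edges.tsv"))
  write_summary_json(summ, file.path(cfg$out_dir, "network_summary.json"))

  if (nrow(net$edges) > 0) {
    res$class_tables <- list(
      disease = class_table(net, "disease", mode = cfg$bdbh_mode,
                            min_shared = cfg$min_shared, seed = cfg$seed),
      subpathway = class_table(net, "subpathway", mode = cfg$bdbh_mode,
                               min_shared = cfg$min_shared, seed = cfg$seed))
    for (side in names(res$class_tables)) {
      utils::write.table(res$class_tables[[side]]$per_class,
                         file.path(cfg$out_dir, paste0("bdbh_", side, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res$diversity <- disease_diversity_table(net)
    utils::write.table(res$diversity,
                       file.path(cfg$out_dir, "disease_diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (summ$n_diseases >= 2 && summ$n_subpathways >= 2) {
      res$clustering <- hierarchical_cluster(net)
      write_cdt(res$clustering, file.path(cfg$out_dir, "clustered_incidence.cdt"))
    }
  }

  label_paths <- cfg[c("disease_genes", "essential_genes",
                       "housekeeping_genes", "tissue_specific_genes")]
  if (all(!vapply(label_paths, is.null, logical(1)))) {
    labels <- gene_class_labels(
      read_gene_list(cfg$disease_genes), read_gene_list(cfg$essential_genes),
      read_gene_list(cfg$housekeeping_genes),
      read_gene_list(cfg$tissue_specific_genes))
    res$profiles <- gene_ratio_profiles(net, subpathways, labels)
    utils::write.table(res$profiles,
                       file.path(cfg$out_dir, "gene_ratio_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$trends <- lapply(
      stats::setNames(nm = c("ratio_disease", "ratio_essential", "ratio_hk",
                             "ratio_ts")),
      function(f) unclass(trend_test(res$profiles, f)))
    jsonlite::write_json(res$trends, file.path(cfg$out_dir, "trends.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(cfg$expression)) {
      expr <- read_expression_matrix(cfg$expression)
      res$coexpression <- coexpression_summary(net, subpathways, labels, expr,
                                               method = cfg$coexpression_method)
      utils::write.table(res$coexpression$per_subpathway,
                         file.path(cfg$out_dir, "coexpression.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if (cfg$null_replicates > 0) {
    res$null_ensemble <- random_null_ensemble(
      diseases, subpathways, background, alpha = cfg$alpha,
      R = cfg$null_replicates, seed = cfg$seed)
    utils::write.table(res$null_ensemble$samples,
                       file.path(cfg$out_dir, "null_ensemble.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(config = unclass(cfg), seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("subpathnet")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "run_manifest.yaml"))
  invisible(res)
}
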