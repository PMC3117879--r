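#' Gene class label sets
#'
#' Bundles the four gene-class lists used in subpathway composition
#' analyses: disease genes, essential genes (human orthologs of
#' mouse-lethal knockouts), housekeeping (HK) genes and tissue-specific
#' (TS) genes. HK and TS are disjoint by definition of their source
#' classification; the other sets may overlap freely.
#'
#' @param disease_genes,essential_genes,housekeeping_genes,tissue_specific_genes
#'   Character vectors of gene IDs.
#' @return A `gene_class_labels` object (named list of sorted unique sets).
#' @export
gene_class_labels <- function(disease_genes = character(0),
                              essential_genes = character(0),
                              housekeeping_genes = character(0),
                              tissue_specific_genes = character(0)) {
  hk <- sort(unique(housekeeping_genes))
  ts <- sort(unique(tissue_specific_genes))
  if (length(intersect(hk, ts)) > 0) {
    stop("housekeeping and tissue-specific gene lists must be disjoint")
  }
  structure(list(disease_genes = sort(unique(disease_genes)),
                 essential_genes = sort(unique(essential_genes)),
                 housekeeping_genes = hk,
                 tissue_specific_genes = ts),
            class = "gene_class_labels")
}

#' Read a one-column gene list
#'
#' One gene ID per line; `#` comments and blank lines skipped.
#'
#' @param file_path Path to the list file.
#' @return Character vector of gene IDs.
#' @export
read_gene_list <- function(file_path) {
  lines <- trimws(readLines(file_path))
  lines[!grepl("^#", lines) & nzchar(lines)]
}

#' Per-subpathway gene-class composition profiles
#'
#' For every subpathway node of the network: its degree (number of linked
#' diseases) and, over its gene set, the fraction of genes in each class.
#' Subpathways with an empty gene set are excluded with a message.
#'
#' @param net A `subpathway_network`.
#' @param subpathways Subpathway table carrying the gene sets.
#' @param labels A `gene_class_labels` object.
#' @return Data frame: `subpathway_id`, `degree`, `n_genes`,
#'   `ratio_disease`, `ratio_essential`, `ratio_hk`, `ratio_ts`.
#' @export
gene_ratio_profiles <- function(net, subpathways, labels) {
  stopifnot(inherits(labels, "gene_class_labels"))
  deg <- network_degrees(net, "subpathway")
  idx <- match(names(deg), subpathways$subpathway_id)
  if (anyNA(idx)) stop("network subpathway missing from subpathway table")
  gsets <- subpathways$genes[idx]
  empty <- lengths(gsets) == 0
  if (any(empty)) {
    message(sum(empty), " subpathway(s) with empty gene set excluded")
  }
  keep <- which(!empty)
  ratio <- function(set) vapply(gsets[keep], function(g) {
    length(intersect(g, set)) / length(g)
  }, numeric(1))
  data.frame(
    subpathway_id = names(deg)[keep],
    degree = unname(deg[keep]),
    n_genes = lengths(gsets[keep]),
    ratio_disease = unname(ratio(labels$disease_genes)),
    ratio_essential = unname(ratio(labels$essential_genes)),
    ratio_hk = unname(ratio(labels$housekeeping_genes)),
    ratio_ts = unname(ratio(labels$tissue_specific_genes)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Linear trend of a gene-class ratio along subpathway degree
#'
#' Ordinary least squares of the chosen ratio on node degree, with the
#' two-sided t-test P-value for the slope. Each subpathway is one point.
#'
#' @param profiles Data frame from [gene_ratio_profiles()].
#' @param ratio_field Name of the ratio column (e.g. `"ratio_disease"`).
#' @return List (`trend_result`): `slope`, `intercept`, `p_value`, `n`.
#' @export
trend_test <- function(profiles, ratio_field) {
  stopifnot(ratio_field %in% names(profiles))
  n <- nrow(profiles)
  if (n < 3) stop("trend test needs >= 3 profiles")
  if (stats::var(profiles$degree) == 0) stop("zero degree variance")
  fit <- stats::lm(profiles[[ratio_field]] ~ profiles$degree)
  cf <- summary(fit)$coefficients
  structure(list(slope = unname(cf[2, 1]), intercept = unname(cf[1, 1]),
                 p_value = unname(cf[2, 4]), n = n),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> slope %.4g (P = %.3g, n = %d)\n",
              x$slope, x$p_value, x$n))
  invisible(x)
}

#' Equal-count binned summary of a scatter
#'
#' Quantile bins on `x` with per-bin mean and standard deviation of `y`,
#' the usual way to overlay a binned trend on a noisy scatter.
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_bins Number of equal-count bins (must not exceed the number of
#'   points).
#' @return Data frame: `bin`, `bin_center` (mean of `x` in the bin),
#'   `mean_y`, `sd_y`, `n`.
#' @export
binned_summary <- function(x, y, n_bins = 10) {
  stopifnot(length(x) == length(y), n_bins >= 1)
  if (n_bins > length(x)) stop("n_bins exceeds number of points")
  ord <- order(x)
  bin <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  bin <- pmin(bin, n_bins)
  xs <- split(x[ord], bin); ys <- split(y[ord], bin)
  data.frame(
    bin = seq_len(n_bins),
    bin_center = vapply(xs, mean, numeric(1)),
    mean_y = vapply(ys, mean, numeric(1)),
    sd_y = vapply(ys, function(v) if (length(v) > 1) stats::sd(v) else 0,
                  numeric(1)),
    n = lengths(xs), row.names = NULL
  )
}

#' Mean pairwise coexpression between two gene groups
#'
#' Mean correlation of expression profiles over all unordered pairs
#' `(a, b)` with `a` in `genesA`, `b` in `genesB`, `a != b`. Within-group
#' calls (`genesA` identical to `genesB`) therefore enumerate the distinct
#' unordered pairs once. Genes absent from the matrix or with zero
#' variance across tissues are dropped before pairing.
#'
#' @param expr Numeric matrix, rows genes (rownames = gene IDs), columns
#'   tissues.
#' @param genesA,genesB Character vectors of gene IDs.
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @return Mean correlation, or `NA_real_` when no admissible pair exists
#'   (an undefined result, deliberately not zero).
#' @export
pairwise_coexpression <- function(expr, genesA, genesB, method = "pearson") {
  usable <- rownames(expr)[apply(expr, 1, stats::sd) > 0]
  a <- intersect(unique(genesA), usable)
  b <- intersect(unique(genesB), usable)
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  all_g <- union(a, b)
  cm <- stats::cor(t(expr[all_g, , drop = FALSE]), method = method)
  pair_seen <- new.env(hash = TRUE)
  vals <- numeric(0)
  for (ga in a) for (gb in b) {
    if (ga == gb) next
    key <- paste(sort(c(ga, gb)), collapse = "\r")
    if (!is.null(pair_seen[[key]])) next
    pair_seen[[key]] <- TRUE
    vals <- c(vals, cm[ga, gb])
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

#' Within-subpathway coexpression contrasts
#'
#' For every subpathway node of the network, computes the average
#' coexpression of six gene-pair groups within its gene set:
#' disease-disease, disease-essential, disease-HK, disease-TS,
#' disease-other ("other" = genes in none of the four label sets) and
#' all-all. The all-all group is the random control: per-group medians
#' across subpathways and a two-sided Wilcoxon rank-sum test of each
#' group's per-subpathway averages against the all-all averages say
#' whether disease genes coexpress with that class more than with a
#' typical subpathway gene.
#'
#' @param net A `subpathway_network`.
#' @param subpathways Subpathway table with gene sets.
#' @param labels A `gene_class_labels` object.
#' @param expr Expression matrix (genes x tissues).
#' @param method Correlation type passed to [pairwise_coexpression()].
#' @return A `coexpression_summary`: list with `per_subpathway` (data frame
#'   of group averages, `NA` where a group has no admissible pair),
#'   `medians` (named vector over subpathways with a defined value) and
#'   `wilcoxon_p` (named vector, groups vs all-all).
#' @export
coexpression_summary <- function(net, subpathways, labels, expr,
                                 method = "pearson") {
  stopifnot(inherits(labels, "gene_class_labels"))
  s_ids <- names(net$subpathway_class)
  idx <- match(s_ids, subpathways$subpathway_id)
  if (anyNA(idx)) stop("network subpathway missing from subpathway table")
  groups <- c("disease_disease", "disease_essential", "disease_hk",
              "disease_ts", "disease_other", "all_all")
  per <- matrix(NA_real_, length(s_ids), length(groups),
                dimnames = list(s_ids, groups))
  labelled <- unique(c(labels$disease_genes, labels$essential_genes,
                       labels$housekeeping_genes,
                       labels$tissue_specific_genes))
  for (i in seq_along(s_ids)) {
    gs <- subpathways$genes[[idx[i]]]
    dg <- intersect(gs, labels$disease_genes)
    per[i, ] <- c(
      pairwise_coexpression(expr, dg, dg, method),
      pairwise_coexpression(expr, dg, intersect(gs, labels$essential_genes), method),
      pairwise_coexpression(expr, dg, intersect(gs, labels$housekeeping_genes), method),
      pairwise_coexpression(expr, dg, intersect(gs, labels$tissue_specific_genes), method),
      pairwise_coexpression(expr, dg, setdiff(gs, labelled), method),
      pairwise_coexpression(expr, gs, gs, method)
    )
  }
  medians <- apply(per, 2, stats::median, na.rm = TRUE)
  control <- per[, "all_all"]
  wil <- vapply(groups[groups != "all_all"], function(gp) {
    v <- per[, gp]
    v <- v[!is.na(v)]
    ctl <- control[!is.na(control)]
    if (length(v) == 0 || length(ctl) == 0) return(NA_real_)
    if (length(unique(c(v, ctl))) == 1) return(1)  # identical samples
    suppressWarnings(stats::wilcox.test(v, ctl)$p.value)
  }, numeric(1))
  structure(list(
    per_subpathway = data.frame(subpathway_id = s_ids, per,
                                stringsAsFactors = FALSE, row.names = NULL),
    medians = medians, wilcoxon_p = wil
  ), class = "coexpression_summary")
}

#' @export
print.coexpression_summary <- function(x, ...) {
  cat("<coexpression_summary> medians across subpathways:\n")
  print(round(x$medians, 3))
  invisible(x)
}
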