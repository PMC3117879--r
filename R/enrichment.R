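#' Hypergeometric over-representation P-value
#'
#' Probability of observing `x` or more annotated genes when `n_d` genes
#' are drawn without replacement from a background of `N_bg` genes of which
#' `m` carry the annotation: `P(X >= x)` for
#' `X ~ Hypergeometric(N_bg, m, n_d)`. The tail is strictly "at least x"
#' (one-sided over-representation), so `x = 0` gives exactly 1.
#'
#' @param x Number of annotated genes among the draws.
#' @param n_d Number of draws (disease genes in the background).
#' @param m Number of annotated genes in the background (subpathway genes).
#' @param N_bg Background size.
#' @return The upper-tail probability, in (0, 1].
#' @export
hypergeom_pvalue <- function(x, n_d, m, N_bg) {
  if (any(c(x, n_d, m, N_bg) < 0) || m > N_bg || n_d > N_bg ||
      x > min(m, n_d)) {
    stop("inconsistent hypergeometric counts: x=", x, " n_d=", n_d,
         " m=", m, " N_bg=", N_bg)
  }
  stats::phyper(x - 1, m, N_bg - m, n_d, lower.tail = FALSE)
}

#' Build disease gene-set table
#'
#' @param disease_id,disease_class Character vectors, one entry per disease.
#' @param genes List of character vectors of gene IDs.
#' @return A data frame with a `genes` list-column.
#' @export
disease_gene_sets <- function(disease_id, disease_class, genes) {
  stopifnot(length(disease_id) == length(disease_class),
            length(disease_id) == length(genes))
  data.frame(disease_id = as.character(disease_id),
             disease_class = as.character(disease_class),
             n_genes = lengths(genes),
             genes = I(lapply(genes, function(g) sort(unique(as.character(g))))),
             stringsAsFactors = FALSE)
}

#' Default enrichment background
#'
#' All genes annotated to at least one enzyme in the pathway collection —
#' the universe the subpathway gene sets are drawn from.
#'
#' @param ann A `gene_annotation_map`.
#' @return Sorted character vector of gene IDs.
#' @export
pathway_background <- function(ann) {
  stopifnot(inherits(ann, "gene_annotation_map"))
  sort(names(ann$gene2ec))
}

#' Enrich one disease gene set against every subpathway
#'
#' For each subpathway with at least one disease gene (`x >= 1`), computes
#' the hypergeometric over-representation P-value of the overlap between
#' the disease's genes and the subpathway's genes, both restricted to the
#' background universe. Disease genes outside the background are dropped
#' from the draw count. No multiple-testing correction is applied by
#' default: pairs are significant when the raw P-value is below `alpha`
#' (set `fdr = TRUE` to threshold Benjamini-Hochberg-adjusted values
#' instead).
#'
#' @param d One row of a disease gene-set table (list with `disease_id`,
#'   `genes`), or a character vector of genes plus `disease_id`.
#' @param subpathways Subpathway table from [mine_collection()].
#' @param background Character vector: the gene universe. Must contain
#'   every subpathway gene.
#' @param alpha Significance cutoff on the P-value (default 0.01).
#' @param fdr If `TRUE`, apply BH adjustment across this disease's tests
#'   before thresholding.
#' @return Data frame with columns `disease_id`, `subpathway_id`, `x`, `m`,
#'   `n_d`, `N_bg`, `p_value`, `significant`; one row per subpathway with
#'   `x >= 1`.
#' @export
enrich_disease <- function(d, subpathways, background, alpha = 0.01,
                           fdr = FALSE) {
  if (length(background) == 0) stop("empty enrichment background")
  stopifnot(alpha > 0, alpha <= 1)
  genes_d <- intersect(unlist(d$genes, use.names = FALSE), background)
  N_bg <- length(background)
  n_d <- length(genes_d)
  spw_genes <- lapply(subpathways$genes, intersect, background)
  x <- vapply(spw_genes, function(g) length(intersect(g, genes_d)), integer(1))
  m <- lengths(spw_genes)
  keep <- which(x >= 1)
  p <- vapply(keep, function(i) hypergeom_pvalue(x[i], n_d, m[i], N_bg),
              numeric(1))
  p_eff <- if (fdr && length(p)) stats::p.adjust(p, "BH") else p
  data.frame(
    disease_id = rep(as.character(d$disease_id), length(keep)),
    subpathway_id = subpathways$subpathway_id[keep],
    x = x[keep], m = m[keep],
    n_d = rep(n_d, length(keep)), N_bg = rep(N_bg, length(keep)),
    p_value = p,
    significant = p_eff < alpha,
    stringsAsFactors = FALSE
  )
}

#' Enrich every disease against every subpathway
#'
#' @param diseases Disease gene-set table ([disease_gene_sets()] or
#'   [read_gad_table()]); disease IDs must be unique.
#' @inheritParams enrich_disease
#' @return Row-bound [enrich_disease()] results, ordered by disease then
#'   subpathway.
#' @export
enrich_all <- function(diseases, subpathways, background, alpha = 0.01,
                       fdr = FALSE) {
  if (anyDuplicated(diseases$disease_id)) {
    stop("duplicate disease_id in disease table")
  }
  if (length(background) == 0) stop("empty enrichment background")
  # vectorized overlap counting via a background x subpathway indicator
  N_bg <- length(background)
  memb <- matrix(FALSE, N_bg, nrow(subpathways),
                 dimnames = list(background, subpathways$subpathway_id))
  for (j in seq_len(nrow(subpathways))) {
    memb[intersect(subpathways$genes[[j]], background), j] <- TRUE
  }
  m <- colSums(memb)
  out <- vector("list", nrow(diseases))
  for (i in seq_len(nrow(diseases))) {
    genes_d <- intersect(diseases$genes[[i]], background)
    n_d <- length(genes_d)
    x <- if (n_d) colSums(memb[genes_d, , drop = FALSE]) else rep(0, ncol(memb))
    keep <- which(x >= 1)
    p <- stats::phyper(x[keep] - 1, m[keep], N_bg - m[keep], n_d,
                       lower.tail = FALSE)
    p_eff <- if (fdr && length(p)) stats::p.adjust(p, "BH") else p
    out[[i]] <- data.frame(
      disease_id = rep(diseases$disease_id[i], length(keep)),
      subpathway_id = subpathways$subpathway_id[keep],
      x = as.integer(x[keep]), m = as.integer(m[keep]),
      n_d = rep(n_d, length(keep)), N_bg = rep(N_bg, length(keep)),
      p_value = as.numeric(p), significant = p_eff < alpha,
      stringsAsFactors = FALSE
    )
  }
  template <- data.frame(disease_id = character(0),
                         subpathway_id = character(0), x = integer(0),
                         m = integer(0), n_d = integer(0), N_bg = integer(0),
                         p_value = numeric(0), significant = logical(0),
                         stringsAsFactors = FALSE)
  res <- do.call(rbind, c(list(template), out, list(make.row.names = FALSE)))
  res <- res[order(res$disease_id, res$subpathway_id, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write / read an enrichment result table
#'
#' @param results Data frame from [enrich_all()].
#' @param path TSV path.
#' @export
write_enrichment_table <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_enrichment_table
#' @export
read_enrichment_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(disease_id = "character",
                                   subpathway_id = "character"))
}
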